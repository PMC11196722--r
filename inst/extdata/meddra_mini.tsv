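llt_name	pt_name	soc_name	primary_soc_flag
ACUTE KIDNEY INJURY	ACUTE KIDNEY INJURY	RENAL AND URINARY DISORDERS	1
ACUTE RENAL FAILURE	ACUTE KIDNEY INJURY	RENAL AND URINARY DISORDERS	1
CHRONIC KIDNEY DISEASE	CHRONIC KIDNEY DISEASE	RENAL AND URINARY DISORDERS	1
CHRONIC RENAL INSUFFICIENCY	CHRONIC KIDNEY DISEASE	RENAL AND URINARY DISORDERS	1
RENAL FAILURE	RENAL FAILURE	RENAL AND URINARY DISORDERS	1
KIDNEY FAILURE	RENAL FAILURE	RENAL AND URINARY DISORDERS	1
HAEMATURIA	HAEMATURIA	RENAL AND URINARY DISORDERS	1
BLOOD IN URINE	HAEMATURIA	RENAL AND URINARY DISORDERS	1
DYSURIA	DYSURIA	RENAL AND URINARY DISORDERS	1
PAINFUL URINATION	DYSURIA	RENAL AND URINARY DISORDERS	1
NEPHROGENIC ANAEMIA	NEPHROGENIC ANAEMIA	RENAL AND URINARY DISORDERS	1
NEPHROGENIC ANAEMIA	NEPHROGENIC ANAEMIA	BLOOD AND LYMPHATIC SYSTEM DISORDERS	0
BLADDER TRANSITIONAL CELL CARCINOMA	BLADDER TRANSITIONAL CELL CARCINOMA	NEOPLASMS BENIGN MALIGNANT AND UNSPECIFIED	1
TRANSITIONAL CELL CANCER OF BLADDER	BLADDER TRANSITIONAL CELL CARCINOMA	NEOPLASMS BENIGN MALIGNANT AND UNSPECIFIED	1
BLADDER TRANSITIONAL CELL CARCINOMA STAGE II	BLADDER TRANSITIONAL CELL CARCINOMA	RENAL AND URINARY DISORDERS	0
FOETAL DEATH	FOETAL DEATH	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
FETAL DEATH	FOETAL DEATH	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
INTRAUTERINE DEATH	FOETAL DEATH	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
ABORTION SPONTANEOUS	ABORTION SPONTANEOUS	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
SPONTANEOUS ABORTION	ABORTION SPONTANEOUS	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
MISCARRIAGE	ABORTION SPONTANEOUS	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
PREMATURE RUPTURE OF MEMBRANES	PREMATURE RUPTURE OF MEMBRANES	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
PREMATURE LABOUR	PREMATURE LABOUR	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
PRETERM LABOUR	PREMATURE LABOUR	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	1
SEPSIS NEONATAL	SEPSIS NEONATAL	INFECTIONS AND INFESTATIONS	1
SEPSIS NEONATAL	SEPSIS NEONATAL	PREGNANCY PUERPERIUM AND PERINATAL CONDITIONS	0
NEONATAL SEPSIS	SEPSIS NEONATAL	INFECTIONS AND INFESTATIONS	1
CONGENITAL RENAL CYST	CONGENITAL RENAL CYST	CONGENITAL FAMILIAL AND GENETIC DISORDERS	1
CONGENITAL RENAL CYST	CONGENITAL RENAL CYST	RENAL AND URINARY DISORDERS	0
RASH	RASH	SKIN AND SUBCUTANEOUS TISSUE DISORDERS	1
SKIN RASH	RASH	SKIN AND SUBCUTANEOUS TISSUE DISORDERS	1
PRURITUS	PRURITUS	SKIN AND SUBCUTANEOUS TISSUE DISORDERS	1
ITCHING	PRURITUS	SKIN AND SUBCUTANEOUS TISSUE DISORDERS	1
URTICARIA	URTICARIA	SKIN AND SUBCUTANEOUS TISSUE DISORDERS	1
HIVES	URTICARIA	SKIN AND SUBCUTANEOUS TISSUE DISORDERS	1
NAUSEA	NAUSEA	GASTROINTESTINAL DISORDERS	1
VOMITING	VOMITING	GASTROINTESTINAL DISORDERS	1
DIARRHOEA	DIARRHOEA	GASTROINTESTINAL DISORDERS	1
DIARRHEA	DIARRHOEA	GASTROINTESTINAL DISORDERS	1
HEADACHE	HEADACHE	NERVOUS SYSTEM DISORDERS	1
DIZZINESS	DIZZINESS	NERVOUS SYSTEM DISORDERS	1
VULVOVAGINAL BURNING SENSATION	VULVOVAGINAL BURNING SENSATION	REPRODUCTIVE SYSTEM AND BREAST DISORDERS	1
VULVAR OEDEMA	VULVAR OEDEMA	REPRODUCTIVE SYSTEM AND BREAST DISORDERS	1
APPLICATION SITE BURNING	APPLICATION SITE BURNING	GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS	1
FATIGUE	FATIGUE	GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS	1
ADVERSE DRUG REACTION	ADVERSE DRUG REACTION	GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS	1
HYPERTENSION	HYPERTENSION	VASCULAR DISORDERS	1
HIGH BLOOD PRESSURE	HYPERTENSION	VASCULAR DISORDERS	1
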