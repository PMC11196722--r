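# Developmental-toxicity screening keywords (synthetic stand-in list).
# One keyword per line; matched as case-insensitive substrings of LLT names.
FOETAL
FETAL
ABORTION
MISCARRIAGE
PREMATURE
PRETERM
NEONATAL
CONGENITAL
STILLBIRTH
INTRAUTERINE
PERINATAL
GESTATION
TERATOGEN
BIRTH DEFECT
EMBRYO
FOETUS
FETUS
DEVELOPMENTAL DELAY
LOW BIRTH WEIGHT
MEMBRANES
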