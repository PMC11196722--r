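# Known ADR list for miconazole (synthetic fixture, not a real label)
Rash
Pruritus
Headache
Nausea
Vomiting
Application site burning
Vulvovaginal burning sensation
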