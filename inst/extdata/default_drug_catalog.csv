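drug_code,name,drug_class,mme_factor,extended_release
MORPHINE-IR-15,morphine immediate release 15 mg tablet,opioid,1,false
MORPHINE-ER-30,morphine sulfate extended release 30 mg tablet,opioid,1,true
HYDROCODONE-5,hydrocodone 5 mg tablet,opioid,1,false
OXYCODONE-10,oxycodone 10 mg tablet,opioid,1.5,false
OXYCODONE-ER-20,oxycodone extended release 20 mg tablet,opioid,1.5,true
HYDROMORPHONE-2,hydromorphone 2 mg tablet,opioid,4,false
CODEINE-30,codeine 30 mg tablet,opioid,0.15,false
TRAMADOL-50,tramadol 50 mg tablet,opioid,0.1,false
FENTANYL-PATCH-25,fentanyl transdermal 25 mcg/hr patch,opioid,2.4,true
DIAZEPAM-5,diazepam 5 mg tablet,benzodiazepine,,false
LORAZEPAM-1,lorazepam 1 mg tablet,benzodiazepine,,false
ALPRAZOLAM-0.5,alprazolam 0.5 mg tablet,benzodiazepine,,false
CLONAZEPAM-0.5,clonazepam 0.5 mg tablet,benzodiazepine,,false
TEMAZEPAM-15,temazepam 15 mg capsule,benzodiazepine,,false
NALOXONE-NASAL-4,naloxone 4 mg nasal spray,naloxone,,false
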