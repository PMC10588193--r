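group,stratum,n_encounters,n_influenced
screening,alert_triggered,2368118,555626
prescription_alert,all,555626,100301
trigger_count,1,419088,70825
trigger_count,2,113887,23603
trigger_count,3,20378,5249
trigger_count,4,2135,579
trigger_count,5,130,43
trigger_count,6,8,2
medication,opioid,412189,64782
medication,benzodiazepine,106468,27268
medication,both,36866,8148
trigger,early_refill,229250,53105
trigger,positive_tox,148968,21936
trigger,rx_3plus_30d,126568,25917
trigger,onsite_admin_2plus,34794,4681
trigger,prior_overdose,25210,4850
trigger,co_prescribed,148103,24755
trigger,extended_release_naive,4142,1007
specialty,behavioral_health,13222,2588
specialty,cancer,21596,5334
specialty,emergency,88698,9879
specialty,long_term_care,331,116
specialty,pain,94143,11248
specialty,primary_care,249611,54625
specialty,medical_specialty,21313,4451
specialty,surgical_specialty,46428,7208
specialty,unknown,20284,4852
facility,ed_urgent_care,98391,11382
facility,inpatient,37757,8785
facility,outpatient,411256,77772
facility,other,8222,2362
prescriber,physician,359913,57711
prescriber,physician_assistant,93525,12354
prescriber,nurse_practitioner,82014,12679
prescriber,other_unknown,20174,17557
ninety_day_alert,all,119153,3634
naloxone_alert,all,105817,2463
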