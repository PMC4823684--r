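"field","type","units","allowed","lo","hi","description"
"case_id","id","","",NA,NA,"unique case identifier"
"subject_kind","enum","","fetus_or_neonate|mother",NA,NA,"who died: the fetus/neonate or the mother"
"gestational_age_weeks","numeric","completed weeks","",4,50,"gestational age at delivery"
"birth_weight_grams","numeric","g","",100,8000,"birth weight"
"signs_of_life","tristate","","present|absent|unknown",NA,NA,"any sign of life at delivery: heartbeat, cry, breathing or movement"
"macerated","tristate","","present|absent|unknown",NA,NA,"maceration of the fetus at delivery"
"age_at_death_days","numeric","days","",0,365,"age at death for live-born infants (completed days)"
"maternal_trauma","tristate","","present|absent|unknown",NA,NA,"maternal trauma during pregnancy: accident, assault or suicide"
"fetal_trauma_signs","tristate","","present|absent|unknown",NA,NA,"fetal trauma at delivery: severe bruising, cephalohematoma, sub-conjunctival hemorrhage, large caput or long-bone fracture"
"major_congenital_anomaly","tristate","","present|absent|unknown",NA,NA,"major visible anomaly: neural tube defect/anencephaly, abdominal wall defect or other visible defect"
"maternal_infection_signs","tristate","","present|absent|unknown",NA,NA,"maternal infection in pregnancy or delivery: malaria or syphilis positive, fever, chills, or significant vaginal/fetal odor at delivery"
"cond_preeclampsia_eclampsia","tristate","","present|absent|unknown",NA,NA,"maternal preeclampsia/eclampsia (BP >=140/90 with proteinuria)"
"cond_obstructed_or_prolonged_labor","tristate","","present|absent|unknown",NA,NA,"obstructed labor or labor lasting more than one day"
"cond_antepartum_hemorrhage","tristate","","present|absent|unknown",NA,NA,"heavy bleeding (>1000 cc) before delivery (abruption/previa)"
"cond_fetal_distress","tristate","","present|absent|unknown",NA,NA,"fetal distress in labor: decreased movements, bradycardia (<120 bpm), tachycardia (>160 bpm) or meconium staining"
"cond_cord_complication","tristate","","present|absent|unknown",NA,NA,"cord prolapse, cord around the neck, compression or rupture"
"cond_breech_presentation","tristate","","present|absent|unknown",NA,NA,"breech presentation"
"cond_twins","tristate","","present|absent|unknown",NA,NA,"twin (multiple) gestation"
"temperature_celsius","numeric","deg C","",25,45,"neonatal body temperature, if measured"
"hot_to_touch","tristate","","present|absent|unknown",NA,NA,"neonate very warm to the touch"
"cool_to_touch","tristate","","present|absent|unknown",NA,NA,"neonate cool to the touch"
"seizures_ge_2_days","tristate","","present|absent|unknown",NA,NA,"fits or seizures starting 2 or more days after birth"
"umbilical_discharge_pus_bleeding","tristate","","present|absent|unknown",NA,NA,"cloudy discharge, pus or bleeding at the umbilical stump"
"pneumonia_signs","tristate","","present|absent|unknown",NA,NA,"pneumonia: chest x-ray, or poor feeding, irritability, tachypnea, retractions, grunting or hypoxemia"
"breathing_difficulty_or_no_cry","tristate","","present|absent|unknown",NA,NA,"breathing difficulty or no cry at birth"
"seizures_lt_2_days","tristate","","present|absent|unknown",NA,NA,"fits or seizures within 2 days of birth"
"resuscitation_at_birth","tristate","","present|absent|unknown",NA,NA,"bag-and-mask or other resuscitation effort at birth"
"pregnancy_weeks_at_death","numeric","completed weeks","",4,50,"gestation at the mother's death (or at the end of the pregnancy for postpartum deaths)"
"weeks_postpartum_at_death","numeric","weeks","",0,52,"weeks postpartum at the mother's death; 0/missing if pregnant"
"induced_abortion","tristate","","present|absent|unknown",NA,NA,"abortion was induced"
"ectopic_pregnancy","tristate","","present|absent|unknown",NA,NA,"ectopic pregnancy"
"seizure_or_unresponsive","tristate","","present|absent|unknown",NA,NA,"one or more convulsions or a state of unresponsiveness"
"hemorrhage_gt_1000cc","tristate","","present|absent|unknown",NA,NA,"blood loss over 1000 cc (about 4 cups) before or after delivery"
"preeclampsia_signs","tristate","","present|absent|unknown",NA,NA,"BP >=140/90 with proteinuria, headache; may include stroke, loss of consciousness or paralysis"
"acute_dyspnea_and_chest_pain","tristate","","present|absent|unknown",NA,NA,"acute shortness of breath together with chest pain"
"medical_condition","tristate","","present|absent|unknown",NA,NA,"coincident medical condition: cancer, cardiac disease, severe anemia, diabetes or renal disease"
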