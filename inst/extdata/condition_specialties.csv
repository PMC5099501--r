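condition,score_column,specialty
Women's health,WomensReproductiveHealthScore,Obstetrics and Gynecology
Women's health,WomensReproductiveHealthScore,Gynecology Oncology
Mental and behavioral health,MentalAndBehavioralHealthScore,Counselor
Mental and behavioral health,MentalAndBehavioralHealthScore,Psychoanalyst
Mental and behavioral health,MentalAndBehavioralHealthScore,Clinical Neuropsychologist
Mental and behavioral health,MentalAndBehavioralHealthScore,Psychologist
Mental and behavioral health,MentalAndBehavioralHealthScore,Psychoanalysis
Mental and behavioral health,MentalAndBehavioralHealthScore,Marriage and Family Therapist
Cancer screening,CancerScreeningScore,Pediatric Oncology
Cancer screening,CancerScreeningScore,Oncology
Cancer screening,CancerScreeningScore,Hematology & Oncology
Cancer screening,CancerScreeningScore,Radiation Oncology
Heart disease,HeartDiseaseTreatmentScore,Cardiologist
Heart disease,HeartDiseaseTreatmentScore,Cardiac Rehabilitation
Heart disease,HeartDiseaseTreatmentScore,Cardiology Technician
Heart disease,HeartDiseaseTreatmentScore,Cardiovascular Diseases
Children and adolescent health,ChildrenAndAdolescentsScore,Pediatrics
Children and adolescent health,ChildrenAndAdolescentsScore,Neonatal Pediatrics
Children and adolescent health,ChildrenAndAdolescentsScore,Pediatrics Critical Care
Diabetes,DiabetesTreatmentScore,Diabetes Educator
Diabetes,DiabetesTreatmentScore,Endocrinology
Diabetes,DiabetesTreatmentScore,Diabetes and Metabolism
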