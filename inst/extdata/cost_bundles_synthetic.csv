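bundle,label,quantity,unit_price
wound_management,first outpatient visit,1,12
wound_management,control visits,2,8
wound_management,minor healing procedures,3,10
wound_management,HbA1c test,1,6
wound_management,lipid profile,1,5
wound_management,X-ray,1,8
wound_management,oral antibiotic course (clindamycin),1,2
debridement,emergency consultation,1,15
debridement,hospital bed-day,6,45
debridement,anesthesiologist evaluation,1,25
debridement,cardiologist evaluation,1,25
debridement,anesthesia and surgical materials,1,90
debridement,debridement procedure,1,180
debridement,intermediate care unit day,1,120
debridement,wound healing procedures,6,12
debridement,pre-surgery tests,1,40
debridement,antibiogram,1,12
debridement,HbA1c test,1,6
debridement,lipid profile,1,5
debridement,X-ray,1,8
debridement,IV antibiotic day (ampicillin/sulbactam),3,20
debridement,oral antibiotic day,11,2
debridement,peripheral line,1,10
debridement,follow-up consultations,4,12
debridement,dressing materials,1,14
minor_amputation,emergency consultation,1,15
minor_amputation,hospital bed-day,10,45
minor_amputation,anesthesiologist evaluation,1,25
minor_amputation,cardiologist evaluation,1,25
minor_amputation,anesthesia and surgical materials,1,150
minor_amputation,amputation procedure,1,400
minor_amputation,intermediate care unit day,2,120
minor_amputation,blood transfusion,1,80
minor_amputation,pre-surgery tests,1,40
minor_amputation,bacteriology study,1,20
minor_amputation,HbA1c test,1,6
minor_amputation,lipid profile,1,5
minor_amputation,white cell count,1,4
minor_amputation,X-ray,1,8
minor_amputation,Doppler echography,1,35
minor_amputation,arteriography,1,90
minor_amputation,MRI,1,180
minor_amputation,tissue biopsy,1,30
minor_amputation,IV antibiotic day (ampicillin/sulbactam),3,20
minor_amputation,oral antibiotic day,11,2
minor_amputation,peripheral line,1,10
minor_amputation,follow-up consultations,6,12
minor_amputation,dressing materials,1,30
minor_amputation,rehabilitation session,40,25
minor_amputation,orthopedic supplies (crutches and orthopedic foot),1,350
minor_amputation,caregiver month,6,301
major_amputation,emergency consultation,1,15
major_amputation,hospital bed-day,19,45
major_amputation,anesthesiologist evaluation,1,25
major_amputation,cardiologist evaluation,1,25
major_amputation,anesthesia and surgical materials,1,200
major_amputation,amputation procedure,1,550
major_amputation,intermediate care unit day,3,120
major_amputation,blood transfusion,1,80
major_amputation,pre-surgery tests,1,40
major_amputation,bacteriology study,1,20
major_amputation,HbA1c test,1,6
major_amputation,lipid profile,1,5
major_amputation,white cell count,1,4
major_amputation,X-ray,1,8
major_amputation,Doppler echography,1,35
major_amputation,arteriography,1,90
major_amputation,MRI,1,180
major_amputation,tissue biopsy,1,30
major_amputation,IV antibiotic day (ampicillin/sulbactam),5,20
major_amputation,oral antibiotic day,16,2
major_amputation,peripheral line,1,10
major_amputation,follow-up consultations,8,12
major_amputation,dressing materials,1,14
major_amputation,rehabilitation session,50,25
major_amputation,orthopedic supplies (crutches and orthopedic leg and wheelchair),1,900
major_amputation,caregiver month,6,405
prevention_sub_optimal,annual physician consultation,1,12
prevention_sub_optimal,annual podiatrist consultation,1,12
prevention_sub_optimal,HbA1c test,1,6
prevention_sub_optimal,lipid profile,1,5
prevention_sub_optimal,creatinine test,1,4
prevention_sub_optimal,electrocardiogram,1,18
prevention_sub_optimal,X-ray,1,8
prevention_standard,physician consultations,6,12
prevention_standard,podiatrist consultation,1,12
prevention_standard,nurse education session,1,8
prevention_standard,HbA1c test,3,6
prevention_standard,lipid profile,1,5
prevention_standard,creatinine test,2,4
prevention_standard,electrocardiogram,2,10
prevention_standard,X-ray,1,8
prevention_standard,protective footwear pair,1,34
prevention_standard_plus_temp,physician consultations,6,12
prevention_standard_plus_temp,podiatrist consultation,1,12
prevention_standard_plus_temp,nurse education session,1,8
prevention_standard_plus_temp,HbA1c test,3,6
prevention_standard_plus_temp,lipid profile,1,5
prevention_standard_plus_temp,creatinine test,2,4
prevention_standard_plus_temp,electrocardiogram,2,10
prevention_standard_plus_temp,X-ray,1,8
prevention_standard_plus_temp,protective footwear pair,1,34
prevention_standard_plus_temp,handheld infrared thermometer,1,118.8
prevention_standard_plus_temp,nurse-assisted daily phone call,365,0.28
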