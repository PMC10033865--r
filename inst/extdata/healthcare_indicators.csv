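category,name,national,instance,comprehensive_index
H,Number of beds,1002,1200,1.98
H,Bed utilization rate,81.50,64.63,2.07
H,Average number of consultations per day,6.3,5.47,1.32
H,Inpatient number per day,2.1,2.9,-3.81
L,Total number of consultations,600801,499438,1.69
L,Number of hospital admissions,31285,38775,-2.39
L,Average disposable income,32189,30949,-0.39
L,Average hospitalization days of discharged patients,8.6,8.28,0.37
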