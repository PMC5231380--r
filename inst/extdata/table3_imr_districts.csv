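conflict_class,district,imr_1982,imr_2002,counterfactual_2002,rate_prewar,rate_conflict
High Conflict,Batticaloa,27,15.2,6.2,-0.066,-0.019
High Conflict,Jaffna,17,6,12.7,-0.027,-0.038
High Conflict,Kilinochchi,n/a,3.9,n/a,n/a,n/a
High Conflict,Mannar,27,6.9,13.1,-0.010,-0.030
High Conflict,Mullaitivu,n/a,8.9,n/a,n/a,n/a
High Conflict,Trincomalee,18,2.5,4.1,-0.060,-0.043
High Conflict,Vavuniya,16,11.8,4.8,-0.058,-0.016
Intermittent Conflict,Ampara,20,7,3.5,-0.076,-0.031
Intermittent Conflict,Anuradhapura,26,17.6,11.6,-0.034,-0.012
Intermittent Conflict,Polonnaruwa,14,16.1,1.7,-0.086,0.031
Intermittent Conflict,Puttalam,24,6.3,13.5,-0.032,-0.040
No Conflict,Badulla,34,15.9,10.7,-0.056,-0.025
No Conflict,Colombo,50,16.2,n/a,n/a,
No Conflict,Galle,34,10.9,13.3,-0.046,-0.032
No Conflict,Gampaha,22,5.2,n/a,n/a,-0.037
No Conflict,Hambantota,18,4.7,4.7,-0.065,-0.035
No Conflict,Kaluthara,20,4,3.6,-0.082,-0.043
No Conflict,Kandy,39,15.8,12.1,-0.065,-0.035
No Conflict,Kegalle,29,9.2,7.4,-0.066,-0.035
No Conflict,Kurunegala,29,10.8,14.4,-0.031,-0.032
No Conflict,Matale,29,7.6,6.3,-0.058,-0.006
No Conflict,Matara,33,5.9,18.7,-0.028,-0.042
No Conflict,Moneragala,13,2,2.6,-0.076,-0.045
No Conflict,Nuwara Eliya,49,16,16.1,-0.054,-0.036
No Conflict,Ratnapura,43,13.5,17.6,-0.044,-0.033
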