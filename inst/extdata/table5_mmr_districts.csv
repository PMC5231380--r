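conflict_class,district,mmr_1982,mmr_2002,counterfactual_2002,rate_prewar,rate_conflict,label,endpoint_1999
High Conflict,Batticaloa,1.30,0.04,0.50,-0.054,-0.028,Rate is worse; outcome is better,TRUE
High Conflict,Jaffna,0.10,0.40,0.01,-0.107,-0.012,Rate and outcome are worse,FALSE
High Conflict,Kilinochi,n/a,1.43,n/a,n/a,n/a,Unable to determine,TRUE
High Conflict,Mannar,0.90,0.63,0.45,-0.014,0.069,Rate is better; outcome is worse,TRUE
High Conflict,Mullaitivu,n/a,0.21,n/a,n/a,n/a,Unable to determine,TRUE
High Conflict,Trincomalee,0.70,n/a,0.37,-0.032,-0.025,Rate is worse,TRUE
High Conflict,Vavuniya,0.30,0.60,0.06,-0.107,-0.010,Rate is worse; outcome is same,TRUE
Intermittent Conflict,Ampara,0.60,0.17,0.12,-0.077,-0.046,Rate and outcome are worse,FALSE
Intermittent Conflict,Anuradhapura,0.20,0.19,0.02,-0.119,-0.036,Rate and outcome are worse,FALSE
Intermittent Conflict,Polonnaruwa,0.40,0.14,0.07,-0.086,-0.047,Rate and outcome are worse,FALSE
Intermittent Conflict,Puttalam,0.30,0.21,0.03,-0.107,-0.043,Rate and outcome are worse,FALSE
No Conflict,Badulla,0.80,0.28,0.27,-0.061,-0.023,Rate and outcome are worse,FALSE
No Conflict,Colombo,0.50,0.12,0.08,-0.088,-0.038,Rate and outcome are worse,FALSE
No Conflict,Galle,0.60,0.11,0.23,-0.047,-0.042,Rate is worse; outcome is better,FALSE
No Conflict,Gampaha,0.30,0.12,n/a,n/a,-0.022,Unable to determine,FALSE
No Conflict,Hambantota,0.80,0.15,0.05,-0.102,-0.033,Rate and outcome are worse,FALSE
No Conflict,Kandy,0.80,0.10,0.18,-0.071,-0.042,Rate is worse; outcome is better,FALSE
No Conflict,Kaluthara,0.50,0.06,0.11,-0.071,-0.042,Rate is worse; outcome is better,FALSE
No Conflict,Kegalle,0.60,0.12,0.13,-0.086,-0.040,Rate is worse; outcome is better,TRUE
No Conflict,Kurunegala,0.60,0.20,0.23,-0.048,-0.035,Rate is worse; outcome is better,FALSE
No Conflict,Matale,1.00,0.12,0.80,-0.013,-0.043,Rate and outcome are better,TRUE
No Conflict,Matara,0.90,0.14,0.53,-0.026,-0.043,Rate and outcome are better,FALSE
No Conflict,Moneragala,0.60,0.15,0.16,-0.065,-0.045,Rate is worse; outcome is better,FALSE
No Conflict,Nuwara Eliya,1.20,0.52,0.37,-0.057,-0.025,Rate and outcome are worse,FALSE
No Conflict,Ratnapura,0.70,0.31,0.11,-0.087,-0.035,Rate and outcome are worse,FALSE
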