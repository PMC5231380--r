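conflict_class,district,label,endpoint_1999
High Conflict,Batticaloa,Rate is worse; MMR is better,TRUE
High Conflict,Jaffna,Rate and MMR are worse,FALSE
High Conflict,Kilinochi,Unable to determine,FALSE
High Conflict,Mannar,Rate is better; MMR is worse,TRUE
High Conflict,Mullaitivu,Unable to determine,FALSE
High Conflict,Trincomalee,Rate is worse,TRUE
High Conflict,Vavuniya,Rate is worse; MMR is same,TRUE
Intermittent Conflict,Ampara,Rate and MMR are worse,FALSE
Intermittent Conflict,Anuradhapura,Rate and MMR are worse,FALSE
Intermittent Conflict,Polonnaruwa,Rate and MMR are worse,FALSE
Intermittent Conflict,Puttalam,Rate and MMR are worse,FALSE
No Conflict,Badulla,Rate and MMR are worse,FALSE
No Conflict,Colombo,Rate and MMR are worse,FALSE
No Conflict,Galle,Rate is worse; MMR is better,FALSE
No Conflict,Gampaha,Unable to determine,FALSE
No Conflict,Hambantota,Rate and MMR are worse,FALSE
No Conflict,Kandy,Rate is worse; MMR is better,FALSE
No Conflict,Kaluthara,Rate is worse; MMR is better,FALSE
No Conflict,Kegalle,Rate is worse; MMR is better,TRUE
No Conflict,Kurunegala,Rate is worse; MMR is better,FALSE
No Conflict,Matale,Rate and MMR are better,TRUE
No Conflict,Matara,Rate and MMR are better,FALSE
No Conflict,Moneragala,Rate is worse; MMR is better,FALSE
No Conflict,Nuwara Eliya,Rate and MMR are worse,FALSE
No Conflict,Ratnapura,Rate and MMR are worse,FALSE
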