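conflict_class,district,label
High Conflict,Batticaloa,Rate and IMR are worse
High Conflict,Jaffna,Rate and IMR are better
High Conflict,Kilinochchi,Unable to determine
High Conflict,Mannar,Rate and IMR are better
High Conflict,Mullaitivu,Unable to determine
High Conflict,Trincomalee,Rate is worse; IMR is better
High Conflict,Vavuniya,Rate and IMR are worse
Intermittent Conflict,Ampara,Rate and IMR are worse
Intermittent Conflict,Anuradhapura,Rate and IMR are worse
Intermittent Conflict,Polonnaruwa,Rate and IMR are worse
Intermittent Conflict,Puttalam,Rate and IMR are better
No Conflict,Badulla,Rate and IMR are worse
No Conflict,Colombo,Unable to determine
No Conflict,Galle,Rate is worse; IMR is better
No Conflict,Gampaha,Unable to determine
No Conflict,Hambantota,Rate is worse; IMR is better
No Conflict,Kaluthara,Rate and IMR are worse
No Conflict,Kandy,Rate and IMR are worse
No Conflict,Kegalle,Rate and IMR are worse
No Conflict,Kurunegala,Rate and IMR are better
No Conflict,Matale,Rate and IMR are worse
No Conflict,Matara,Rate and IMR are better
No Conflict,Moneragala,Rate is worse; IMR is better
No Conflict,Nuwara Eliya,Rate is worse; IMR is better
No Conflict,Ratnapura,Rate is worse; IMR is better
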