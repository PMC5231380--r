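unit_id,indicator,year,value,source
NATIONAL,IMR,1982,34.00,World Bank
NATIONAL,IMR,2000,19.30,World Bank
NATIONAL,IMR,2002,18.20,World Bank
NATIONAL,MMR,1972,1.30,Ministry of Health
NATIONAL,MMR,1982,0.60,Ministry of Health
NATIONAL,MMR,2002,0.14,Ministry of Health
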