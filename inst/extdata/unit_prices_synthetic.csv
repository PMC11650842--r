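"item","unit","price_nrs"
"consultation","visit",250
"screening","test",626
"bed_day","night",1500
"transport_trip","round trip",50
"food_serving","serving",30
"call_minute","minute",2
"sms","message",1
"trainer_session","session",3000
"peer_supporter","person-trial",2500
"materials","cluster",2000
"minimum_wage","day",668
"exchange_rate","NRs per USD",125.2
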