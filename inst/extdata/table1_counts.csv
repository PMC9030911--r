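variable,level,social,fear,control
district,D1,51,48,42
district,D2,55,61,62
district,D3,24,22,26
education,elementary_or_none,86,85,90
education,junior_high_or_above,41,38,35
married,yes,83,85,84
married,no,44,41,44
has_children,yes,79,82,81
has_children,no,47,42,47
phone,yes,128,126,124
phone,no,0,0,2
driving_setting,urban,25,29,30
driving_setting,suburban,24,32,23
driving_setting,both,78,69,70
night,never,34,42,36
night,sometimes,41,43,45
night,usually,32,26,33
night,always,22,19,16
baseline,consistent,69,69,69
baseline,inconsistent,61,62,61
speeding,never,15,18,20
speeding,sometimes,41,42,36
speeding,usually,65,64,70
speeding,always,9,6,4
weekend,never,9,3,7
weekend,sometimes,21,36,33
weekend,usually,30,33,32
weekend,always,70,59,58
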