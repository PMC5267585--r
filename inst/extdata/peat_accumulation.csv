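species,rate_t_c_ha_yr
AtlanticWhiteCedar,0.36
CypressGum,0.14
MapleGum,0.12
PondPine,0.17
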