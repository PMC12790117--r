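"column","type","units","allowed","required","min","max"
"site_id","id","","",TRUE,,
"country","character","","",FALSE,,
"sdi_quintile","enum","","low|low_middle|middle|high_middle",FALSE,,
"gbd_region","enum","","SSA|SA|LA|SLA|CE|NA_ME",FALSE,,
"urban","logical","","",FALSE,,
"academic","logical","","",FALSE,,
"census_gt50","logical","","",FALSE,,
"picu","logical","","",FALSE,,
"intensivist_weekday","logical","","",FALSE,,
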