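year,deaths_synthetic,deaths_heroin,us_population,hud_past_year,treatment_past_year,treatment_from_hud,treatment_is_scaled
2002,1295,2089,287300000,214000,,,FALSE
2003,1400,2080,289800000,189000,,,FALSE
2004,1664,1878,292400000,270000,,107200,TRUE
2005,1742,2009,295000000,227000,,130600,TRUE
2006,2707,2088,297800000,324000,,259100,TRUE
2007,2213,2399,300600000,214000,,138200,TRUE
2008,2306,3041,303500000,283000,,156000,TRUE
2009,2946,3278,306300000,369000,,221300,TRUE
2010,3007,3036,309000000,361000,,188300,TRUE
2011,2666,4397,311600000,426000,,200700,TRUE
2012,2628,5925,314000000,467000,,201400,TRUE
2013,3105,8257,316400000,517000,,246800,TRUE
2014,5544,10574,318700000,586000,,270000,FALSE
2015,9580,12989,320900000,591000,,242000,FALSE
2016,19413,15469,323000000,626000,,235000,FALSE
2017,28466,15482,325100000,652000,,358000,FALSE
2018,31335,14996,327100000,526000,,291500,TRUE
2019,36259,14019,329100000,438000,,321000,TRUE
2020,56883,13058,331000000,,,,FALSE
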