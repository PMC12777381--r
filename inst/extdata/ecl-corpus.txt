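# Regression corpus: one ECL query per line, jointly covering every
# implemented grammar construct. All concept ids resolve in demo_fixture().
64572001
64572001 |Disease (disorder)|
<< 64572001
< 64572001
> 22298006
>> 22298006
*
<< 64572001 OR << 71388002
<< 64572001 AND << 900000002
(<< 64572001 OR << 71388002) MINUS << 22298006
<< 64572001 MINUS 22298006
<< (64572001 OR 71388002)
< (900000003)
(* MINUS << 71388002) AND << 900000001
<< 64572001 : 42752001 = << 22298006
<< 64572001 : { 116676008 = << 55641003 }
<< 64572001 |Disease (disorder)| : { 116676008 |Associated morphology (attribute)| = << 55641003 |Infarct (morphologic abnormality)| OR 42752001 |Due to (attribute)| = << 22298006 |Myocardial infarction (disorder)| }
<< 64572001 : { 363698007 = << 119199005 }
<< 64572001 : { 363698007 = << 39607008 }
(<< 64572001 : { 116676008 = << 55641003 }) AND << 900000002
<< 64572001 : [0..0] 116676008 = *
<< 64572001 : { 116676008 != 900000012 }
<< 900000004 : R 116676008 = << 64572001
<< 900000003 : R 363698007 = << 64572001
<< 64572001 : [1..2] 116676008 = << 900000004
<< 64572001 : { 116676008 = (55641003 OR 900000016) }
<< 64572001 : { 116676008 = << 55641003 AND 363698007 = << 900000003 }
<< 64572001 : { 116676008 = << 55641003 } AND { 363698007 = << 900000003 }
<< 64572001 : 42752001 = 22298006, 363698007 = 39607008
<< 64572001 : [0..1] { 116676008 = << 55641003 }
<< 64572001 : { [2..*] 116676008 = << 900000004 }
* : 116676008 = << 55641003
(* MINUS << 71388002) : 363698007 = << 900000003
>> 119199005 AND << 900000003
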