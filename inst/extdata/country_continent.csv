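country,continent
US,North America
CA,North America
MX,North America
PR,North America
CU,North America
DO,North America
GT,North America
CR,North America
PA,North America
BR,South America
AR,South America
CL,South America
CO,South America
PE,South America
VE,South America
EC,South America
UY,South America
BO,South America
PY,South America
GB,Europe
FR,Europe
DE,Europe
IT,Europe
ES,Europe
PT,Europe
NL,Europe
BE,Europe
CH,Europe
AT,Europe
SE,Europe
NO,Europe
DK,Europe
FI,Europe
IE,Europe
PL,Europe
CZ,Europe
SK,Europe
HU,Europe
RO,Europe
BG,Europe
GR,Europe
HR,Europe
RS,Europe
SI,Europe
UA,Europe
RU,Europe
TR,Asian
CN,Asian
JP,Asian
KR,Asian
IN,Asian
PK,Asian
BD,Asian
ID,Asian
PH,Asian
VN,Asian
TH,Asian
MY,Asian
SG,Asian
TW,Asian
HK,Asian
IL,Asian
SA,Asian
AE,Asian
IR,Asian
IQ,Asian
QA,Asian
KW,Asian
JO,Asian
LB,Asian
ZA,Africa
NG,Africa
EG,Africa
MA,Africa
DZ,Africa
TN,Africa
KE,Africa
ET,Africa
GH,Africa
TZ,Africa
UG,Africa
SN,Africa
AU,Oceania
NZ,Oceania
FJ,Oceania
PG,Oceania
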