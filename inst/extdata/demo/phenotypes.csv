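sample_id,age,sex,stage,rpd,pa,hrf,irora,crora
S00001,57.3964493227332,female,none,,,,,
S00002,74.0413602026278,male,intermediate,1,0,0,0,0
S00003,65.0163838578425,male,early,,,,,
S00004,68.4341056742271,female,intermediate,1,0,1,0,0
S00005,64.6906361632675,female,intermediate,0,0,0,0,0
S00006,75.5202994126962,male,late,,,,,
S00007,82.321739049471,male,intermediate,0,0,1,0,0
S00008,58.5612014736202,male,intermediate,0,0,1,0,0
S00009,77.0691676049009,female,intermediate,0,0,0,0,0
S00010,69.1478285599355,female,intermediate,0,0,1,0,0
S00011,66.5943339269301,male,intermediate,0,0,0,0,0
S00012,85.30599277339,male,late,,,,,
S00013,69.0907162332639,female,intermediate,1,0,1,0,0
S00014,68.5499631911267,female,none,,,,,
S00015,65.3740214116371,male,early,,,,,
S00016,76.4945384662742,male,intermediate,0,0,1,0,0
S00017,67.5773909901589,male,early,,,,,
S00018,71.9191024398014,female,intermediate,0,0,1,0,0
S00019,71.4815067457897,female,intermediate,0,1,1,0,0
S00020,72.1582191243888,female,intermediate,0,1,0,0,1
S00021,84.4657021378117,male,late,,,,,
S00022,72.612093777168,male,intermediate,0,1,1,0,0
S00023,71.0993579282009,male,intermediate,0,0,1,0,0
S00024,68.1517469192239,male,intermediate,0,1,0,1,0
S00025,74.8224613652629,female,intermediate,0,1,1,0,0
S00026,61.9215698467181,female,intermediate,0,0,0,0,0
S00027,67.6541562805819,male,intermediate,0,0,0,0,0
S00028,72.159720879442,female,intermediate,0,1,0,0,0
S00029,68.6534367450755,female,late,,,,,
S00030,66.7667293767189,male,intermediate,0,0,0,1,0
S00031,78.9135188386154,female,late,,,,,
S00032,71.85994829143,male,early,,,,,
S00033,65.7046977072763,female,late,,,,,
S00034,67.2530636437256,male,intermediate,1,1,0,0,0
S00035,83.9335554651494,female,late,,,,,
S00036,72.0868740239067,female,intermediate,0,1,0,0,0
S00037,78.4900919426154,female,late,,,,,
S00038,74.2561926084245,female,intermediate,1,1,1,0,0
S00039,66.5516302169827,male,intermediate,0,0,0,0,1
S00040,81.9244847591741,female,intermediate,0,0,1,0,0
S00041,82.0478511597772,male,late,,,,,
S00042,73.3290837984165,female,intermediate,0,0,0,1,0
S00043,59.5249512027253,male,intermediate,1,1,1,0,0
S00044,72.5701685805068,female,intermediate,1,1,1,0,0
S00045,64.6864591181125,male,none,,,,,
S00046,73.2233920869801,female,none,,,,,
S00047,73.3114139354848,female,intermediate,1,0,1,0,1
S00048,69.3407847797663,female,early,,,,,
S00049,71.45626393503,female,intermediate,1,1,1,0,0
S00050,77.5451122676386,female,intermediate,0,1,0,0,0
S00051,74.7395009906532,female,intermediate,0,0,0,0,0
S00052,81.2304113033301,male,intermediate,0,0,0,1,0
S00053,58.3170012477007,female,intermediate,1,1,1,0,0
S00054,74.0012690335268,female,intermediate,0,0,1,0,0
S00055,69.3538829922323,male,late,,,,,
S00056,63.7359359126051,female,intermediate,0,1,0,0,0
S00057,69.3041047154706,female,intermediate,0,0,0,0,0
S00058,75.2144729292252,female,intermediate,1,0,1,0,1
S00059,72.2016095364564,male,intermediate,1,1,0,0,0
S00060,68.3787087535386,female,intermediate,1,0,0,0,0
S00061,65.948573045,female,intermediate,0,0,1,0,0
S00062,84.7520391204119,male,intermediate,1,0,0,1,0
S00063,79.7912839425853,female,intermediate,0,0,1,0,0
S00064,82.2128832148924,female,intermediate,1,0,0,0,0
S00065,76.3445245289759,female,none,,,,,
S00066,68.265150759954,male,intermediate,0,0,0,0,1
S00067,69.8396289647578,male,intermediate,0,1,0,0,0
S00068,68.9882137504091,male,late,,,,,
S00069,74.7578767815732,female,intermediate,0,0,0,0,0
S00070,75.0735369517817,female,late,,,,,
S00071,59.5861427899442,male,intermediate,1,0,1,0,0
S00072,72.8962936622981,male,intermediate,0,0,1,0,0
S00073,67.689005256227,female,intermediate,0,1,0,0,0
S00074,69.2395012416333,female,intermediate,0,1,1,0,0
S00075,66.6047300092331,female,intermediate,0,0,1,0,0
S00076,68.7209771878138,female,intermediate,1,0,0,0,0
S00077,72.5497732713419,female,intermediate,1,0,0,0,0
S00078,68.9402682393021,female,late,,,,,
S00079,80.1921823029024,male,intermediate,0,1,0,0,0
S00080,61.1126767869298,female,intermediate,0,1,0,0,0
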