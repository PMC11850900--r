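 0.0030339313066555392, 0.7367971102606389877,-0.6761071021461010355
-0.6323984977372044680,-0.3228562277292079674,-0.7041562300201515967
 0.0420876850751055256, 0.9378646231969612890,-0.3444395089426308121
-0.7153653745955425025, 0.5647545804432577699, 0.4114664563462482882
 0.1125166301090958221,-0.9931591773409471635,-0.0312226906647382757
 0.4397684526343242917,-0.8501947872232488157,-0.2894348490524710216
-0.6457060961328479065,-0.4379615088444375748,-0.6255024813600510436
-0.1784647174924888502,-0.9621565782328234118, 0.2059248978963708898
 0.0619923427378480038,-0.0739279544236276093,-0.9953349220220354399
-0.9748101118994784153,-0.0877665407845097112, 0.2050421421494792451
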