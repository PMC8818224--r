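behaviour,cefas,gcdc
crouch,638,1087
lie,32056,54544
sit,2389,4061
stand,13842,23536
head movement,1429,2405
crouching stalk,96,163
lying stalk,11692,19933
sitting stalk,119,204
standing stalk,1330,2201
walking stalk,3024,5132
trotting stalk,1267,2129
walk,6651,11161
trot,1295,2165
canter,3039,4985
gallop,4154,6976
pounce,87,141
other,20466,32549
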