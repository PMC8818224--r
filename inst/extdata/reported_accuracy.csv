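model,behaviour,cefas,gcdc
fine,crouch,35.6,49.3
fine,lie,92.6,95.3
fine,sit,79.7,86.6
fine,stand,90.4,87.8
fine,head movement,55.1,65.9
fine,crouching stalk,78.9,65.8
fine,lying stalk,93.5,92.8
fine,sitting stalk,96.3,100.0
fine,standing stalk,78.5,79.9
fine,walking stalk,58.2,65.1
fine,trotting stalk,47.4,56.3
fine,walk,75.8,77.9
fine,trot,37.4,53.5
fine,canter,51.0,54.8
fine,gallop,78.2,69.4
fine,pounce,4.8,56.0
medium,head movement,53.4,57.1
medium,crouching stalk,63.2,65.8
medium,lying stalk,93.2,92.3
medium,sitting stalk,92.6,100.0
medium,standing stalk,77.7,78.6
medium,walk,73.1,74.6
medium,trot,34.5,50.2
medium,canter,49.1,53.4
medium,gallop,77.5,67.9
medium,sedentary,95.0,95.4
medium,moving stalk,59.2,69.2
coarse,head movement,50.3,61.3
coarse,active,86.9,88.3
coarse,inactive,95.5,95.0
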