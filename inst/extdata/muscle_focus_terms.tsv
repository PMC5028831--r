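index	name
1	skeletal muscle tissue development
2	positive regulation of skeletal muscle fiber development
3	skeletal muscle fiber development
4	positive regulation of myoblast differentiation
5	positive regulation of muscle cell differentiation
6	muscle cell fate commitment
7	muscle cell differentiation
8	sarcomere organization
9	myofibril assembly
10	myoblast differentiation
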