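landmark,x,y,z
Tr,0,80,10
G,0,25,12
Ft_L,-62.06,40,0
Ft_R,62.06,40,0
Ex_L,-48.285,10,0
Ex_R,48.285,10,0
En_L,-16.5,10,5
En_R,16.5,10,5
N,0,15,8
Prn,0,-24.59,33.91
Sn,0,-30,15
Al_L,-16.355,-25,8
Al_R,16.355,-25,8
Sbal_L,-10,-28,12
Sbal_R,10,-28,12
Ls,0,-38,14
Sto,0,-45,12
Li,0,-52,13
Ch_L,-25,-45,8
Ch_R,25,-45,8
Pg,0,-75,10
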