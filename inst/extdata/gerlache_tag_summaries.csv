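deployment_id,surface_s,dive_s,total_s
mn170218-31,16186.2,20824.0,37010.2
mn170220-30,3290.3,5561.6,8851.9
mn180227-40,11330.8,12016.0,23346.8
mn180227-41,23012.5,37736.1,60748.6
mn180227-43,27609.2,36505.8,64115.0
mn180227-44,25090.5,69660.9,94751.4
mn180227-45,212.4,685.2,897.6
mn180227-46,17653.9,46775.4,64429.3
mn180227-47,309.8,619.5,929.3
mn180228-47,12358.4,29965.0,42323.4
mn190203-22,24306.4,71692.5,95998.9
mn190203-23,12394.2,25526.3,37920.5
mn190205-27,19229.8,45189.7,64419.5
mn190205-40,23349.2,63803.5,87152.7
mn190212-27,6658.6,18529.3,25187.9
mn190212-40,3146.4,18547.3,21693.7
mn190215-40,7653.3,35539.3,43192.6
mn190225-40,12137.1,15920.2,28057.3
mn190225-44,1448.0,992.8,2440.8
mn190228-42,41582.5,51995.0,93577.5
mn190228-44,27466.5,11853.8,39320.3
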