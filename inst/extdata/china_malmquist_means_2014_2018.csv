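unit_id,effch,techch,pech,sech,tfpch
Shanghai,1,0.993,1,1,0.993
Anhui,0.976,0.985,0.977,0.999,0.961
Shandong,0.980,0.988,0.986,0.993,0.967
Jiangsu,0.990,0.993,1.014,0.977,0.984
Zhejiang,0.994,0.988,1,0.994,0.982
Yunnan,0.986,0.986,0.985,1,0.971
Sichuan,0.978,0.987,0.854,1.146,0.965
Guangdong,0.972,0.988,1,0.972,0.960
Guangxi,0.954,0.985,0.876,1.089,0.940
Henan,0.967,0.987,0.971,0.996,0.955
Hubei,0.968,0.987,0.858,1.128,0.955
Hunan,0.946,0.985,0.946,1,0.932
Guizhou,1.010,0.981,1.010,1,0.991
Chongqing,0.960,0.978,0.954,1.006,0.939
Inner Mongolia,0.975,0.978,0.976,1,0.954
Beijing,1.004,0.988,1.004,1,0.992
Tianjin,1,0.978,1,1,0.978
Shanxi,0.987,0.979,0.988,0.998,0.966
Hebei,0.965,0.985,0.969,0.996,0.951
Jilin,0.987,0.976,0.987,1,0.964
Liaoning,0.979,0.986,0.981,0.998,0.965
Heilongjiang,0.954,0.973,0.958,0.995,0.928
Shaanxi,0.975,0.983,0.976,0.999,0.958
Ningxia,1,0.955,1,1,0.955
Gansu,0.962,0.981,0.968,0.994,0.944
Jiangxi,0.954,0.984,0.953,1.001,0.939
Fujian,0.995,0.985,0.996,0.999,0.980
Hainan,0.990,0.956,1,0.994,0.951
Xinjiang,0.998,0.971,1.015,0.983,0.970
Qinghai,0.991,0.949,0.982,1.009,0.940
Tibet,1,0.928,1,1,0.928
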