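state,A,B,C,D,E,F
Aguascalientes,1.000,1.000,0.233,,,
Baja California,1.000,1.000,0.154,,0.092,0.067
Baja California Sur,0.461,0.486,0.094,,0.088,0.096
Campeche,0.512,0.416,0.166,0.120,,0.185
Mexico City,0.973,0.829,0.294,0.082,0.303,0.149
Chiapas,1.000,1.000,0.203,1.000,0.388,0.116
Chihuahua,0.606,0.618,0.109,,0.082,
Coahuila,0.854,0.829,0.090,,0.141,
Colima,0.791,1.000,0.063,,,0.196
Durango,0.727,0.735,0.240,,0.460,
Guanajuato,1.000,1.000,0.200,0.110,0.467,
Guerrero,1.000,0.729,0.180,,0.278,0.121
Hidalgo,0.765,0.555,0.153,0.092,,
Jalisco,0.928,0.763,0.146,1.000,0.211,0.025
Mexico State,1.000,1.000,0.408,0.000,0.446,
Michoacán,0.736,0.629,0.127,,0.223,0.181
Morelos,0.774,0.485,0.116,,0.467,
Nayarit,0.634,0.691,0.343,,,0.036
Nuevo León,0.922,1.000,0.210,0.153,0.466,
Oaxaca,0.864,0.652,0.322,0.134,0.242,0.059
Puebla,1.000,0.616,0.207,0.087,0.247,
Querétaro,1.000,0.966,0.212,,,
Quintana Roo,0.756,0.740,0.145,,0.121,0.011
San Luis Potosí,1.000,0.959,0.145,1.000,0.073,
Sinaloa,0.590,0.727,0.152,,0.258,0.242
Sonora,0.780,0.600,0.096,,0.149,0.114
Tabasco,0.963,0.634,0.293,0.156,0.175,1.000
Tamaulipas,0.632,0.757,0.099,0.120,0.171,0.099
Tlaxcala,0.659,0.507,0.223,,,
Veracruz,0.869,0.474,0.160,0.193,0.300,0.157
Yucatán,0.806,0.701,0.237,,0.122,0.023
Zacatecas,0.628,0.797,0.154,,0.094,
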