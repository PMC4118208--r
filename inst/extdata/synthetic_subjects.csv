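subject_id,weight_kg,dose_mg,time_min,conc_mg_per_L
S001,126.02146025876733,31.505365064691834,2,6.51346710073219
S001,126.02146025876733,31.505365064691834,2.5,5.192654196305606
S001,126.02146025876733,31.505365064691834,3,4.938105708931372
S001,126.02146025876733,31.505365064691834,3.5,4.042206095727867
S001,126.02146025876733,31.505365064691834,4,3.319926329016392
S001,126.02146025876733,31.505365064691834,4.5,3.0054625131234336
S001,126.02146025876733,31.505365064691834,5,2.6824508780145653
S002,77.2451964488871,19.311299112221775,2,5.487443081764907
S002,77.2451964488871,19.311299112221775,2.5,4.550772029979337
S002,77.2451964488871,19.311299112221775,3,3.776626727061071
S002,77.2451964488871,19.311299112221775,3.5,3.2514275910423343
S002,77.2451964488871,19.311299112221775,4,2.374366657964613
S002,77.2451964488871,19.311299112221775,4.5,2.2658362403465535
S002,77.2451964488871,19.311299112221775,5,1.7928243242071673
S003,84.27990485390357,21.069976213475893,2,4.38433908294174
S003,84.27990485390357,21.069976213475893,2.5,3.804149726647341
S003,84.27990485390357,21.069976213475893,3,3.0755295934840308
S003,84.27990485390357,21.069976213475893,3.5,2.786760540658327
S003,84.27990485390357,21.069976213475893,4,2.366079527283767
S003,84.27990485390357,21.069976213475893,4.5,2.240587691910717
S003,84.27990485390357,21.069976213475893,5,1.9010942292018906
S004,88.22789868408476,22.05697467102119,2,4.31567638526403
S004,88.22789868408476,22.05697467102119,2.5,3.4981867365769754
S004,88.22789868408476,22.05697467102119,3,2.864084101402276
S004,88.22789868408476,22.05697467102119,3.5,2.5529846158142755
S004,88.22789868408476,22.05697467102119,4,1.8951116620057245
S004,88.22789868408476,22.05697467102119,4.5,1.6396306942100907
S004,88.22789868408476,22.05697467102119,5,1.383203383410441
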