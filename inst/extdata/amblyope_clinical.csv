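subject_id,age,sex,amblyopic_eye,va_logmar_od,va_logmar_os,type
A1,32,F,OS,0,0.7,anisometropic
A2,25,M,OS,-0.1,0.14,anisometropic
A3,35,M,OD,0.84,-0.08,anisometropic
A4,24,F,OS,0,0.5,anisometropic
A5,21,M,OS,-0.1,0.6,anisometropic
A6,21,M,OS,-0.1,0.6,anisometropic
A7,26,F,OS,-0.14,0.22,anisometropic
A8,30,M,OD,0.18,-0.02,anisometropic
A9,27,M,OS,-0.06,0.32,anisometropic
A10,21,M,OD,0.74,-0.08,anisometropic
A11,26,M,OD,0.42,-0.1,anisometropic
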