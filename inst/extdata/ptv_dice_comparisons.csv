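vol_a,vol_b,patient,dice
1PTV_GDM,PTV,1,0.58
1PTV_GDM,PTV,2,0.72
1PTV_GDM,PTV,3,0.73
1PTV_GDM,PTV,4,0.71
1PTV_GDM,PTV,5,0.82
1PTV_GDM,PTV,6,0.83
1PTV_GDM,PTV,7,0.73
2PTV_GDM,PTV,1,0.59
2PTV_GDM,PTV,2,0.78
2PTV_GDM,PTV,4,0.75
2PTV_GDM,PTV,5,0.87
2PTV_GDM,PTV,6,0.70
1PTV_GDM,2PTV_GDM,1,0.86
1PTV_GDM,2PTV_GDM,2,0.87
1PTV_GDM,2PTV_GDM,4,0.92
1PTV_GDM,2PTV_GDM,5,0.94
1PTV_GDM,2PTV_GDM,6,0.87
1PTV_GDM,PTV_MIM,1,0.71
1PTV_GDM,PTV_MIM,2,0.75
1PTV_GDM,PTV_MIM,3,0.83
1PTV_GDM,PTV_MIM,4,0.81
1PTV_GDM,PTV_MIM,5,0.86
1PTV_GDM,PTV_MIM,6,0.90
1PTV_GDM,PTV_MIM,7,0.84
1PTV_GDM-SUM,PTV_MIM,1,0.77
1PTV_GDM-SUM,PTV_MIM,2,0.71
1PTV_GDM-SUM,PTV_MIM,3,0.89
1PTV_GDM-SUM,PTV_MIM,4,0.85
1PTV_GDM-SUM,PTV_MIM,5,0.84
1PTV_GDM-SUM,PTV_MIM,6,0.90
1PTV_GDM-SUM,PTV_MIM,7,0.85
2PTV_GDM,PTV_MIM,1,0.71
2PTV_GDM,PTV_MIM,2,0.76
2PTV_GDM,PTV_MIM,4,0.85
2PTV_GDM,PTV_MIM,5,0.88
2PTV_GDM,PTV_MIM,6,0.77
2PTV_GDM-SUM,PTV_MIM,1,0.79
2PTV_GDM-SUM,PTV_MIM,2,0.72
2PTV_GDM-SUM,PTV_MIM,4,0.84
2PTV_GDM-SUM,PTV_MIM,5,0.88
2PTV_GDM-SUM,PTV_MIM,6,0.78
1PTV_GDM,PTV_VELO,1,0.80
1PTV_GDM,PTV_VELO,2,0.84
1PTV_GDM,PTV_VELO,3,0.84
1PTV_GDM,PTV_VELO,4,0.84
1PTV_GDM,PTV_VELO,5,0.90
1PTV_GDM,PTV_VELO,6,0.92
1PTV_GDM,PTV_VELO,7,0.80
1PTV_GDM-SUM,PTV_VELO,1,0.85
1PTV_GDM-SUM,PTV_VELO,2,0.88
1PTV_GDM-SUM,PTV_VELO,3,0.83
1PTV_GDM-SUM,PTV_VELO,4,0.87
1PTV_GDM-SUM,PTV_VELO,5,0.91
1PTV_GDM-SUM,PTV_VELO,6,0.91
1PTV_GDM-SUM,PTV_VELO,7,0.86
2PTV_GDM,PTV_VELO,1,0.77
2PTV_GDM,PTV_VELO,2,0.86
2PTV_GDM,PTV_VELO,4,0.85
2PTV_GDM,PTV_VELO,5,0.91
2PTV_GDM,PTV_VELO,6,0.80
2PTV_GDM-SUM,PTV_VELO,1,0.80
2PTV_GDM-SUM,PTV_VELO,2,0.86
2PTV_GDM-SUM,PTV_VELO,4,0.87
2PTV_GDM-SUM,PTV_VELO,5,0.90
2PTV_GDM-SUM,PTV_VELO,6,0.86
PTV_MIM,PTV_VELO,1,0.85
PTV_MIM,PTV_VELO,2,0.73
PTV_MIM,PTV_VELO,3,0.90
PTV_MIM,PTV_VELO,4,0.92
PTV_MIM,PTV_VELO,5,0.84
PTV_MIM,PTV_VELO,6,0.87
PTV_MIM,PTV_VELO,7,0.81
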