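ncRNA_001	drug_001
ncRNA_001	drug_003
ncRNA_002	drug_002
ncRNA_002	drug_004
ncRNA_002	drug_008
ncRNA_003	drug_003
ncRNA_003	drug_005
ncRNA_003	drug_007
ncRNA_004	drug_002
ncRNA_004	drug_006
ncRNA_004	drug_008
ncRNA_005	drug_003
ncRNA_005	drug_005
ncRNA_005	drug_007
ncRNA_006	drug_004
ncRNA_006	drug_008
ncRNA_007	drug_001
ncRNA_007	drug_005
ncRNA_007	drug_007
ncRNA_008	drug_002
ncRNA_008	drug_006
ncRNA_008	drug_007
ncRNA_009	drug_001
ncRNA_009	drug_003
ncRNA_009	drug_005
ncRNA_009	drug_007
ncRNA_010	drug_006
ncRNA_010	drug_007
ncRNA_010	drug_008
ncRNA_011	drug_003
ncRNA_011	drug_006
ncRNA_011	drug_007
ncRNA_012	drug_002
ncRNA_012	drug_004
ncRNA_012	drug_006
ncRNA_012	drug_008
ncRNA_013	drug_003
ncRNA_013	drug_005
ncRNA_013	drug_007
ncRNA_014	drug_002
ncRNA_014	drug_004
ncRNA_014	drug_007
ncRNA_014	drug_008
ncRNA_015	drug_001
ncRNA_015	drug_003
ncRNA_015	drug_005
ncRNA_016	drug_004
ncRNA_016	drug_006
ncRNA_016	drug_008
ncRNA_017	drug_003
ncRNA_017	drug_007
ncRNA_018	drug_002
ncRNA_018	drug_006
ncRNA_018	drug_008
ncRNA_019	drug_001
ncRNA_019	drug_005
ncRNA_020	drug_001
ncRNA_020	drug_004
ncRNA_020	drug_006
ncRNA_020	drug_008
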