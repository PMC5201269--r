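gene_id	occ_chip_e6	occ_union	occ_overlap	enr_myoconv	enr_sorted_embryo	enr_L1_bwm	req_function	req_phenotype	req_localization
daf-21	1	1	1	1	0	0	1	0	0
unc-45	1	1	1	0	1	0	0	1	0
hsp-12.2	1	1	0	0	0	1	0	0	1
sip-1	1	0	0	1	1	0	0	0	0
cct-2	0	1	0	1	0	1	1	1	0
cct-7	0	0	1	0	1	1	1	0	1
hsp-12.1	0	0	0	0	0	0	0	1	1
dnj-24	0	0	0	1	1	1	1	1	1
unc-23	0	0	0	1	0	0	1	0	0
C01G10.8	0	0	0	0	0	0	0	0	0
fkb-6	0	0	0	0	0	0	0	0	0
hsp-17	0	0	0	0	0	0	0	0	0
chap-001	1	1	0	0	1	0	0	1	0
chap-002	1	0	1	0	0	1	0	0	1
chap-003	0	1	1	1	1	0	1	1	0
chap-004	1	1	1	1	0	1	1	0	1
chap-005	1	0	0	0	1	1	0	1	1
chap-006	0	1	0	1	1	1	1	1	1
chap-007	0	0	1	1	0	0	1	0	0
chap-008	1	1	0	0	1	0	0	1	0
chap-009	1	0	1	0	0	1	0	0	1
chap-010	0	1	1	1	1	0	1	1	0
chap-011	1	1	1	1	0	1	0	0	0
chap-012	1	0	0	0	1	1	0	0	0
chap-013	0	1	0	1	1	1	0	0	0
chap-014	0	0	1	1	0	0	0	0	0
chap-015	1	1	0	0	1	0	0	0	0
chap-016	1	0	1	0	0	1	0	0	0
chap-017	0	1	1	1	1	0	0	0	0
chap-018	1	1	1	1	0	1	0	0	0
chap-019	1	0	0	0	1	1	0	0	0
chap-020	0	1	0	1	1	1	0	0	0
chap-021	0	0	1	1	0	0	0	0	0
chap-022	1	1	0	0	1	0	0	0	0
chap-023	1	0	1	0	0	1	0	0	0
chap-024	0	1	1	1	1	0	0	0	0
chap-025	1	1	1	1	0	1	0	0	0
chap-026	1	0	0	0	1	1	0	0	0
chap-027	0	1	0	1	1	1	0	0	0
chap-028	0	0	1	1	0	0	0	0	0
chap-029	1	1	0	0	1	0	0	0	0
chap-030	1	0	1	0	0	1	0	0	0
chap-031	0	1	1	1	1	0	0	0	0
chap-032	1	1	1	1	0	1	0	0	0
chap-033	1	0	0	0	1	1	0	0	0
chap-034	0	1	0	0	0	0	0	0	0
chap-035	0	0	1	0	0	0	0	0	0
chap-036	1	1	0	0	0	0	0	0	0
chap-037	1	0	1	0	0	0	0	0	0
chap-038	0	1	1	0	0	0	0	0	0
chap-039	1	1	1	0	0	0	0	0	0
chap-040	1	0	0	0	0	0	0	0	0
chap-041	0	1	0	0	0	0	0	0	0
chap-042	0	0	1	0	0	0	0	0	0
chap-043	1	1	0	0	0	0	0	0	0
chap-044	1	0	1	0	0	0	0	0	0
chap-045	0	1	1	0	0	0	0	0	0
chap-046	1	1	1	0	0	0	0	0	0
chap-047	1	0	0	0	0	0	0	0	0
chap-048	0	1	0	0	0	0	0	0	0
chap-049	0	0	1	0	0	0	0	0	0
chap-050	1	1	0	0	0	0	0	0	0
chap-051	1	0	1	0	0	0	0	0	0
chap-052	0	1	1	0	0	0	0	0	0
chap-053	1	1	1	0	0	0	0	0	0
chap-054	1	0	0	0	0	0	0	0	0
chap-055	0	1	0	0	0	0	0	0	0
chap-056	0	0	1	0	0	0	0	0	0
chap-057	0	0	0	1	1	1	0	0	0
chap-058	0	0	0	1	0	0	0	0	0
chap-059	0	0	0	0	1	0	0	0	0
chap-060	0	0	0	0	0	1	0	0	0
chap-061	0	0	0	1	1	0	0	0	0
chap-062	0	0	0	0	0	0	1	0	1
chap-063	0	0	0	0	0	0	0	1	1
chap-064	0	0	0	0	0	0	1	1	1
chap-065	0	0	0	0	0	0	1	0	0
chap-066	0	0	0	0	0	0	0	1	0
chap-067	0	0	0	0	0	0	0	0	1
chap-068	0	0	0	0	0	0	0	0	0
chap-069	0	0	0	0	0	0	0	0	0
chap-070	0	0	0	0	0	0	0	0	0
chap-071	0	0	0	0	0	0	0	0	0
chap-072	0	0	0	0	0	0	0	0	0
chap-073	0	0	0	0	0	0	0	0	0
chap-074	0	0	0	0	0	0	0	0	0
chap-075	0	0	0	0	0	0	0	0	0
chap-076	0	0	0	0	0	0	0	0	0
chap-077	0	0	0	0	0	0	0	0	0
chap-078	0	0	0	0	0	0	0	0	0
chap-079	0	0	0	0	0	0	0	0	0
chap-080	0	0	0	0	0	0	0	0	0
chap-081	0	0	0	0	0	0	0	0	0
chap-082	0	0	0	0	0	0	0	0	0
chap-083	0	0	0	0	0	0	0	0	0
chap-084	0	0	0	0	0	0	0	0	0
chap-085	0	0	0	0	0	0	0	0	0
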