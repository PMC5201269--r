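gene_id	family
daf-21	Hsp90/cochaperone
unc-45	other
hsp-12.2	sHsp
sip-1	sHsp
cct-2	Hsp60/10
cct-7	Hsp60/10
hsp-12.1	sHsp
dnj-24	Hsp40/NEF
unc-23	other
C01G10.8	Hsp90/cochaperone
fkb-6	other
hsp-17	sHsp
chap-001	Hsp70
chap-002	Hsp40/NEF
chap-003	Hsp60/10
chap-004	Hsp90/cochaperone
chap-005	sHsp
chap-006	other
chap-007	Hsp70
chap-008	Hsp40/NEF
chap-009	Hsp60/10
chap-010	Hsp90/cochaperone
chap-011	sHsp
chap-012	other
chap-013	Hsp70
chap-014	Hsp40/NEF
chap-015	Hsp60/10
chap-016	Hsp90/cochaperone
chap-017	sHsp
chap-018	other
chap-019	Hsp70
chap-020	Hsp40/NEF
chap-021	Hsp60/10
chap-022	Hsp90/cochaperone
chap-023	sHsp
chap-024	other
chap-025	Hsp70
chap-026	Hsp40/NEF
chap-027	Hsp60/10
chap-028	Hsp90/cochaperone
chap-029	sHsp
chap-030	other
chap-031	Hsp70
chap-032	Hsp40/NEF
chap-033	Hsp60/10
chap-034	Hsp90/cochaperone
chap-035	sHsp
chap-036	other
chap-037	Hsp70
chap-038	Hsp40/NEF
chap-039	Hsp60/10
chap-040	Hsp90/cochaperone
chap-041	sHsp
chap-042	other
chap-043	Hsp70
chap-044	Hsp40/NEF
chap-045	Hsp60/10
chap-046	Hsp90/cochaperone
chap-047	sHsp
chap-048	other
chap-049	Hsp70
chap-050	Hsp40/NEF
chap-051	Hsp60/10
chap-052	Hsp90/cochaperone
chap-053	sHsp
chap-054	other
chap-055	Hsp70
chap-056	Hsp40/NEF
chap-057	Hsp60/10
chap-058	Hsp90/cochaperone
chap-059	sHsp
chap-060	other
chap-061	Hsp70
chap-062	Hsp40/NEF
chap-063	Hsp60/10
chap-064	Hsp90/cochaperone
chap-065	sHsp
chap-066	other
chap-067	Hsp70
chap-068	Hsp40/NEF
chap-069	Hsp60/10
chap-070	Hsp90/cochaperone
chap-071	sHsp
chap-072	other
chap-073	Hsp70
chap-074	Hsp40/NEF
chap-075	Hsp60/10
chap-076	Hsp90/cochaperone
chap-077	sHsp
chap-078	other
chap-079	Hsp70
chap-080	Hsp40/NEF
chap-081	Hsp60/10
chap-082	Hsp90/cochaperone
chap-083	sHsp
chap-084	other
chap-085	Hsp70
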