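snp_id	phenotype	beta_sign	available	passed_qc
snp039	small_vldl	-1	FALSE	TRUE
snp058	small_vldl	-1	FALSE	TRUE
snp055	small_vldl	-1	FALSE	TRUE
snp021	small_vldl	-1	TRUE	TRUE
snp009	small_vldl	-1	TRUE	TRUE
snp020	small_vldl	-1	FALSE	TRUE
snp036	small_vldl	-1	FALSE	TRUE
snp034	small_vldl	-1	TRUE	FALSE
snp002	small_vldl	+1	TRUE	TRUE
snp015	small_vldl	+1	TRUE	TRUE
snp007	small_vldl	-1	TRUE	TRUE
snp041	small_vldl	+1	TRUE	TRUE
snp060	small_vldl	+1	TRUE	TRUE
snp023	small_vldl	+1	TRUE	TRUE
snp010	medium_vldl	-1	TRUE	TRUE
snp012	medium_vldl	-1	TRUE	TRUE
snp047	medium_vldl	-1	TRUE	TRUE
snp028	medium_vldl	-1	TRUE	TRUE
snp043	medium_vldl	+1	TRUE	TRUE
snp015	medium_vldl	+1	TRUE	TRUE
snp055	medium_vldl	-1	FALSE	TRUE
snp030	medium_vldl	-1	TRUE	TRUE
snp046	medium_vldl	+1	TRUE	TRUE
snp024	medium_vldl	+1	TRUE	TRUE
snp032	medium_vldl	-1	TRUE	TRUE
snp016	medium_vldl	+1	TRUE	TRUE
snp060	medium_vldl	+1	TRUE	TRUE
snp057	medium_vldl	+1	TRUE	TRUE
snp012	large_vldl	+1	TRUE	TRUE
snp014	large_vldl	-1	TRUE	TRUE
snp009	large_vldl	+1	TRUE	TRUE
snp035	large_vldl	-1	TRUE	TRUE
snp048	large_vldl	-1	TRUE	TRUE
snp024	large_vldl	-1	TRUE	TRUE
snp038	large_vldl	+1	TRUE	TRUE
snp013	large_vldl	-1	TRUE	TRUE
snp023	large_vldl	-1	TRUE	TRUE
snp034	large_vldl	+1	TRUE	FALSE
snp030	large_vldl	+1	TRUE	TRUE
snp058	large_vldl	-1	FALSE	TRUE
snp060	large_vldl	-1	TRUE	TRUE
snp027	large_vldl	+1	TRUE	TRUE
snp022	vldl_total	+1	TRUE	TRUE
snp044	vldl_total	-1	TRUE	TRUE
snp003	vldl_total	-1	TRUE	TRUE
snp040	vldl_total	-1	TRUE	TRUE
snp046	vldl_total	-1	TRUE	TRUE
snp058	vldl_total	+1	FALSE	TRUE
snp029	vldl_total	-1	TRUE	TRUE
snp047	vldl_total	-1	TRUE	TRUE
snp013	vldl_total	-1	TRUE	TRUE
snp011	vldl_total	-1	TRUE	TRUE
snp051	vldl_total	+1	TRUE	TRUE
snp045	vldl_total	-1	TRUE	TRUE
snp052	vldl_total	+1	TRUE	TRUE
snp001	vldl_total	-1	TRUE	TRUE
snp036	vldl_diameter	-1	FALSE	TRUE
snp007	vldl_diameter	-1	TRUE	TRUE
snp032	vldl_diameter	-1	TRUE	TRUE
snp024	vldl_diameter	+1	TRUE	TRUE
snp022	vldl_diameter	+1	TRUE	TRUE
snp048	vldl_diameter	+1	TRUE	TRUE
snp053	vldl_diameter	-1	TRUE	TRUE
snp058	vldl_diameter	-1	FALSE	TRUE
snp006	vldl_diameter	+1	TRUE	TRUE
snp035	vldl_diameter	-1	TRUE	TRUE
snp017	vldl_diameter	+1	TRUE	TRUE
snp042	vldl_diameter	+1	TRUE	TRUE
snp023	vldl_diameter	-1	TRUE	TRUE
snp037	vldl_diameter	-1	TRUE	TRUE
snp026	small_ldl	-1	TRUE	TRUE
snp027	small_ldl	+1	TRUE	TRUE
snp033	small_ldl	-1	TRUE	TRUE
snp057	small_ldl	-1	TRUE	TRUE
snp031	small_ldl	-1	TRUE	TRUE
snp024	small_ldl	+1	TRUE	TRUE
snp012	small_ldl	-1	TRUE	TRUE
snp060	small_ldl	+1	TRUE	TRUE
snp021	small_ldl	+1	TRUE	TRUE
snp039	small_ldl	+1	FALSE	TRUE
snp048	small_ldl	-1	TRUE	TRUE
snp009	small_ldl	-1	TRUE	TRUE
snp054	small_ldl	+1	TRUE	TRUE
snp053	small_ldl	-1	TRUE	TRUE
snp040	large_ldl	+1	TRUE	TRUE
snp055	large_ldl	-1	FALSE	TRUE
snp046	large_ldl	+1	TRUE	TRUE
snp054	large_ldl	+1	TRUE	TRUE
snp039	large_ldl	+1	FALSE	TRUE
snp050	large_ldl	+1	TRUE	TRUE
snp035	large_ldl	+1	TRUE	TRUE
snp037	large_ldl	+1	TRUE	TRUE
snp041	large_ldl	-1	TRUE	TRUE
snp005	large_ldl	-1	TRUE	TRUE
snp016	large_ldl	+1	TRUE	TRUE
snp011	large_ldl	-1	TRUE	TRUE
snp021	large_ldl	+1	TRUE	TRUE
snp020	large_ldl	+1	FALSE	TRUE
snp003	ldl_total	-1	TRUE	TRUE
snp057	ldl_total	+1	TRUE	TRUE
snp006	ldl_total	-1	TRUE	TRUE
snp030	ldl_total	-1	TRUE	TRUE
snp024	ldl_total	-1	TRUE	TRUE
snp049	ldl_total	-1	TRUE	TRUE
snp045	ldl_total	+1	TRUE	TRUE
snp059	ldl_total	+1	TRUE	TRUE
snp051	ldl_total	-1	TRUE	TRUE
snp058	ldl_total	-1	FALSE	TRUE
snp018	ldl_total	+1	TRUE	TRUE
snp022	ldl_total	+1	TRUE	TRUE
snp016	ldl_total	-1	TRUE	TRUE
snp060	ldl_diameter	+1	TRUE	TRUE
snp009	ldl_diameter	+1	TRUE	TRUE
snp052	ldl_diameter	-1	TRUE	TRUE
snp049	ldl_diameter	+1	TRUE	TRUE
snp032	ldl_diameter	-1	TRUE	TRUE
snp055	ldl_diameter	-1	FALSE	TRUE
snp024	ldl_diameter	+1	TRUE	TRUE
snp002	ldl_diameter	-1	TRUE	TRUE
snp047	ldl_diameter	-1	TRUE	TRUE
snp043	ldl_diameter	+1	TRUE	TRUE
snp033	ldl_diameter	-1	TRUE	TRUE
snp039	ldl_diameter	+1	FALSE	TRUE
snp045	ldl_diameter	-1	TRUE	TRUE
snp059	small_hdl	-1	TRUE	TRUE
snp058	small_hdl	-1	FALSE	TRUE
snp060	small_hdl	-1	TRUE	TRUE
snp042	small_hdl	-1	TRUE	TRUE
snp004	small_hdl	-1	TRUE	TRUE
snp032	small_hdl	+1	TRUE	TRUE
snp051	small_hdl	-1	TRUE	TRUE
snp026	small_hdl	+1	TRUE	TRUE
snp052	small_hdl	+1	TRUE	TRUE
snp019	small_hdl	-1	TRUE	TRUE
snp030	small_hdl	+1	TRUE	TRUE
snp039	small_hdl	-1	FALSE	TRUE
snp008	small_hdl	+1	TRUE	TRUE
snp035	medium_hdl	+1	TRUE	TRUE
snp030	medium_hdl	-1	TRUE	TRUE
snp053	medium_hdl	+1	TRUE	TRUE
snp015	medium_hdl	+1	TRUE	TRUE
snp033	medium_hdl	+1	TRUE	TRUE
snp043	medium_hdl	+1	TRUE	TRUE
snp009	medium_hdl	+1	TRUE	TRUE
snp004	medium_hdl	-1	TRUE	TRUE
snp040	medium_hdl	-1	TRUE	TRUE
snp042	medium_hdl	-1	TRUE	TRUE
snp038	medium_hdl	+1	TRUE	TRUE
snp052	medium_hdl	-1	TRUE	TRUE
snp039	medium_hdl	-1	FALSE	TRUE
snp015	large_hdl	-1	TRUE	TRUE
snp047	large_hdl	+1	TRUE	TRUE
snp040	large_hdl	+1	TRUE	TRUE
snp013	large_hdl	+1	TRUE	TRUE
snp058	large_hdl	-1	FALSE	TRUE
snp026	large_hdl	-1	TRUE	TRUE
snp043	large_hdl	-1	TRUE	TRUE
snp021	large_hdl	+1	TRUE	TRUE
snp055	large_hdl	-1	FALSE	TRUE
snp035	large_hdl	-1	TRUE	TRUE
snp030	large_hdl	+1	TRUE	TRUE
snp037	large_hdl	+1	TRUE	TRUE
snp044	large_hdl	-1	TRUE	TRUE
snp049	hdl_total	-1	TRUE	TRUE
snp059	hdl_total	-1	TRUE	TRUE
snp013	hdl_total	+1	TRUE	TRUE
snp018	hdl_total	-1	TRUE	TRUE
snp001	hdl_total	+1	TRUE	TRUE
snp042	hdl_total	-1	TRUE	TRUE
snp025	hdl_total	+1	TRUE	TRUE
snp044	hdl_total	-1	TRUE	TRUE
snp034	hdl_total	+1	TRUE	FALSE
snp052	hdl_total	-1	TRUE	TRUE
snp020	hdl_total	+1	FALSE	TRUE
snp047	hdl_total	-1	TRUE	TRUE
snp036	hdl_total	+1	FALSE	TRUE
snp004	hdl_diameter	-1	TRUE	TRUE
snp055	hdl_diameter	-1	FALSE	TRUE
snp027	hdl_diameter	+1	TRUE	TRUE
snp045	hdl_diameter	+1	TRUE	TRUE
snp016	hdl_diameter	+1	TRUE	TRUE
snp001	hdl_diameter	+1	TRUE	TRUE
snp018	hdl_diameter	+1	TRUE	TRUE
snp005	hdl_diameter	+1	TRUE	TRUE
snp021	hdl_diameter	+1	TRUE	TRUE
snp050	hdl_diameter	+1	TRUE	TRUE
snp058	hdl_diameter	+1	FALSE	TRUE
snp056	hdl_diameter	-1	TRUE	TRUE
snp033	hdl_diameter	+1	TRUE	TRUE
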