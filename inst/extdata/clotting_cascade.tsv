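source	target	line_value
factor_xiia	factor_xia	10
kallikrein	factor_xiia	10
hmw_kininogen	kallikrein	10
factor_xia	factor_ixa	10
factor_ixa	factor_viiia:factor_ixa	10
factor_viiia	factor_viiia:factor_ixa	10
factor_viiia:factor_ixa	factor_xa	10
tissue_factor	tf:factor_viia	10
factor_viia	tf:factor_viia	10
factor_vii	factor_viia	10
tf:factor_viia	factor_xa	10
factor_xa	factor_va:factor_xa	10
factor_va	factor_va:factor_xa	10
factor_va:factor_xa	thrombin	10
thrombin	fibrin	10
fibrin	fibrin_multimer	10
fibrin_multimer	crosslinked_fibrin_clot	10
factor_xiiia	crosslinked_fibrin_clot	10
factor_xiia	factor_viia	10
factor_xa	factor_viia	10
factor_xa	thrombin	10
factor_xa	factor_va	10
factor_xa	factor_viiia	10
thrombin	factor_xiiia	10
thrombomodulin	thrombin:thrombomodulin	10
apc:protein_s	factor_viiia	10
vwf	vwf:factor_viii	10
factor_viii	vwf:factor_viii	10
vwf:factor_viii	factor_viiia	10
plasminogen	plasmin	10
fibrin	plasmin	10
kallikrein	plasmin	10
tfpi	tf:factor_viia	10
tfpi	factor_xa	10
tf:factor_viia	factor_viia	10
thrombin	protein_c	10
thrombin	factor_viii	10
kallikrein	plasminogen	10
factor_xiia	factor_xi	10
vwf	factor_viii	10
plasmin	fibrinogen	10
kallikrein	hmw_kininogen	10
antithrombin_iii	tf:factor_viia	10
protein_s	activated_protein_c	10
factor_xii	factor_xiia	10
prekallikrein	kallikrein	10
factor_ix	factor_ixa	10
factor_viii	factor_viiia	10
factor_x	factor_xa	10
factor_v	factor_va	10
prothrombin	thrombin	10
fibrinogen	fibrin	10
factor_xiii	factor_xiiia	10
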