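metric	count
not_detected	6365
enriched	64
group_enriched	156
enhanced	167
mixed	4048
expressed_in_all	9250
glomeruli	11
proximal_tubule	120
distal_tubule	9
collecting_duct	8
collecting_duct_intercalated	3
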