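!Series_title	"synthetic mini cell-type atlas (hand-written example fixture)"
!Series_summary	"Two purified cell types, two replicate arrays each; g00001 and g00002 are macrophage markers, g00003 is a fibroblast marker."
!Sample_title	"mac_rep1"	"mac_rep2"	"fib_rep1"	"fib_rep2"
!Sample_characteristics_cell_type	"macrophage"	"macrophage"	"fibroblast"	"fibroblast"
!series_matrix_table_begin
"ID_REF"	"mac_rep1"	"mac_rep2"	"fib_rep1"	"fib_rep2"
"g00001"	640	660	5	6
"g00002"	1280	1150	11	9
"g00003"	4	6	512	498
"g00004"	100	104	98	101
"g00005"	55	49	52	50
"g00006"	210	198	205	201
!series_matrix_table_end
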