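# Printed inputs transcribed from the published genome report
# (assembly summary, repeat-annotation table, variant totals, k-mer
# profile, GO annotation counts). Values are exact as printed.
key	value
kmer_number	17016192556
kmer_peak_depth	57
assembly_size_fn	270300000
assembly_size_fv	220400000
snp_total	4561825
indel_total	846301
te_total_len_fn	117216089
te_total_len_fv	76805372
classI_len_fn	57063567
classI_len_fv	49183869
classI_ltr_len_fn	265376
classI_copia_len_fn	16264615
classI_gypsy_len_fn	28207381
classI_line_len_fn	8315089
classI_sine_len_fn	195484
classII_len_fn	46284298
tir_len_fn	36948539
tir_len_fv	16869199
gene_total	28780
go_bp	9890
go_mf	9534
go_cc	6395
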