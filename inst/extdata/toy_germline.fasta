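>IGHV3-23*01 segment=V decoy=false regions=FR1:1-25,CDR1:26-33,FR2:34-50,CDR2:51-58,FR3:59-96
EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAISGSGGSTYYADSVKGRFTISRDNSKNTLY
LQMNSLRAEDTAVYYC
>IGHV3-30*01 segment=V decoy=false regions=FR1:1-25,CDR1:26-33,FR2:34-50,CDR2:51-58,FR3:59-96
QVQLVESGGGVVQPGRSLRLSCAASGFTFSSYGMHWVRQAPGKGLEWVAVISYDGSNKYYADSVKGRFTISRDNSKNTLY
LQMNSLRAEDTAVYYC
>IGHV3-7*01 segment=V decoy=false regions=FR1:1-25,CDR1:26-33,FR2:34-50,CDR2:51-58,FR3:59-96
EVQLVESGGGLVQPGGSLRLSCAASGFTFSSYWMSWVRQAPGKGLEWVANIKQDGSEKYYVDSVKGRFTISRDNAKNSLY
LQMNSLRAEDTAVYYC
>IGHV4-39*01 segment=V decoy=false regions=FR1:1-25,CDR1:26-35,FR2:36-52,CDR2:53-59,FR3:60-97
QLQLQESGPGLVKPSETLSLTCTVSGGSISSSSYYWSWIRQPPGKGLEWIGSIYYSGSTYYNPSLKSRVTISVDTSKNQF
SLKLSSVTAADTAVYYC
>IGHV4-34*01 segment=V decoy=false regions=FR1:1-25,CDR1:26-33,FR2:34-50,CDR2:51-57,FR3:58-95
QVQLQQWGAGLLKPSETLSLTCAVYGGSFSGYYWSWIRQPPGKGLEWIGEINHSGSTYYNPSLKSRVTISVDTSKNQFSL
KLSSVTAADTAVYYC
>IGHV1-69*01 segment=V decoy=false regions=FR1:1-25,CDR1:26-33,FR2:34-50,CDR2:51-58,FR3:59-96
QVQLVQSGAEVKKPGSSVKVSCKASGGTFSSYAISWVRQAPGQGLEWMGGIIPIFGTANYAQKFQGRVTITADESTSTAY
MELSSLRSEDTAVYYC
>IGHV3-NL1*01 segment=V decoy=true regions=FR1:1-25,CDR1:26-33,FR2:34-50,CDR2:51-58,FR3:59-96
EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAISGSGGGTYYADSVKGRFTISRDNAKNTLY
LQMNSLRAEDTALYYC
>IGHV1-45*01 segment=V decoy=true regions=FR1:1-25,CDR1:26-33,FR2:34-50,CDR2:51-58,FR3:59-96
QMQLVQSGAEVKKPGASVKVSCKASGYTFTSYAISWVRQAPGQGLEWMGWINAGNGNTNYAQKFQGRVTITADESTNTAY
MELSSLRSEDTAVYYC
>IGHV4-28*01 segment=V decoy=true regions=FR1:1-25,CDR1:26-35,FR2:36-52,CDR2:53-59,FR3:60-97
QVQLQESGPGLVKPSGTLSLTCAVSGYSISSSNWWGSWVRQPPGKGLEWIGEIYHSGSTNYNPSLKSRVTISVDKSKNQF
SLKLSSVTAADTAVYYC
>IGHD3-10*01 segment=D decoy=false
GYSSGWYG
>IGHD2-2*01 segment=D decoy=false
DIVLMVYAI
>IGHD6-19*01 segment=D decoy=false
GIAVAGTG
>IGHJ1*01 segment=J decoy=false fr4_motif=7
AEYFQHWGQGTLVTVSS
>IGHJ2*01 segment=J decoy=false fr4_motif=7
YWYFDLWGRGTLVTVSS
>IGHJ3*01 segment=J decoy=false fr4_motif=6
DAFDVWGQGTMVTVSS
>IGHJ4*01 segment=J decoy=false fr4_motif=5
YFDYRGQGTLVTVSS
>IGHJ5*01 segment=J decoy=false fr4_motif=6
NWFDPWGQGTLVTVSS
>IGHJ6*01 segment=J decoy=false fr4_motif=10
YYYYYGMDVWGQGTTVTVSS
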