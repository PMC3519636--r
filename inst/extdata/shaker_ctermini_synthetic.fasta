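>NvShak1_cterm_synthetic terminal 4-mer as published; upstream residues synthetic filler
MSGDESKLLNRAEQSPHTTV
>NvShak2_cterm_synthetic terminal 4-mer as published; upstream residues synthetic filler
MSGDESKLLNRAEQSPETLL
>NvShak3_cterm_synthetic terminal 4-mer as published; upstream residues synthetic filler
MSGDESKLLNRAEQSPETPV
>NvShak4_cterm_synthetic terminal 4-mer as published; upstream residues synthetic filler
MSGDESKLLNRAEQSPETGV
>NvShak5_cterm_synthetic terminal 4-mer as published; upstream residues synthetic filler
MSGDESKLLNRAEQSPQTSV
>NvShak6_cterm_synthetic terminal 4-mer as published; upstream residues synthetic filler
MSGDESKLLNRAEQSPDGFV
>NvShakR10_cterm_synthetic terminal 4-mer as published; upstream residues synthetic filler
MSGDESKLLNRAEQSPEFTV
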