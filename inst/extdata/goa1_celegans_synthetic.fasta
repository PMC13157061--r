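>GOA-1_celegans_synthetic reconstruction of C. elegans Galpha-o (not a database record)
MGCTMSQEERAALERSKMIDRNLREDGEKAAREVKLLLLGAGESGKSTIVKQMKIIHEDG
YSEEECKQYKVVVYSNTIQSLIAIIRAMGNLQIDFGESARADDARQLFVLAGSAEEGVMT
PELAGVIKRLWRDGGVQACFSRSREYQLNDSASYYLNDLDRISQSNYIPTQQDVLRTRVK
TTGIVETHFTFKELYFKMFDVGGQRSERKKWIHCFEGVTAIIFCVAMSEYDQVLHEDETT
NRMHESMKLFDSICNNKWFTDTSIILFLNKKDLFEEKIKRSPLTICYPEYTGSNTYEEAA
AYIQCQFEDLNRRKDTKEIYTHFTCATDTKNVQFVFDAVTDVIIKNNLKECGLY
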