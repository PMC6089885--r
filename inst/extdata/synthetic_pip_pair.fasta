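>synthetic_pip_like_A synthetic demo sequence (invented for examples; not a UniProt entry)
MEGKEEDVRVGANKFSERQPIGTAAQGTDDKDYKEPPPAPLFEPGELKSWSFYRAGIAEF
IATFLFLYITVLTVMGVSKSTSKCATVGIQGIAWAFGGMIFALVYCTAGISGGHINPAVT
FGLFLARKLSLTRAVFYMVMQCLGAICGAGVVKGFQQGLYMGNGGGANVVAPGYTKGDGL
GAEIVGTFILVYTVFSATDAKRNARDSHVPVLAPLPIGFAVFLVHLATIPITGTGINPAR
SLGAAIIYNKDHAWDDHWIFWVGPFIGAALAALYHQVVIRAIPFKSRA
>synthetic_pip_like_B synthetic demo sequence (invented for examples; not a UniProt entry)
MAKDIEAVPGEGFQTRDYQDPPPAPLIDAEELTKWSLYRAVIAEFIATLLFLYITVLTVI
GYKSQTDAAASGADAACGGVGVLGIAWAFGGMIFILVYCTAGISGGHINPAVTFGLFLAR
KVSLVRAVMYMVAQCLGAICGVGLVKAFQSSYYTRYGGGANELSAGYSKGTGLAAEIIGT
FVLVYTVFSATDPKRSARDSHVPVLAPLPIGFAVFMVHLATIPITGTGINPARSFGAAVI
YNNEKAWDDQWIFWVGPFIGAAIAAFYHQFILRAGAIKALGSFRSNA
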