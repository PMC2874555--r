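accession	description	status
ARGP820101	Hydrophobicity index	rejected
BIOV880101	Information value for accessibility; average fraction 35%	selected
BIOV880102	Information value for accessibility; average fraction 23%	selected
BLAS910101	Scaled side chain hydrophobicity values	selected
BLAS910101	Scaled side chain hydrophobicity values	rejected
BULH740101	Surface tension of amino acid solutions: A hydrophobicity scale of the amino acid residues	rejected
FASG760101	Molecular weight	rejected
HOPA770101	Hydration number	selected
KRIW710101	Side chain interaction parameter	selected
KRIW790101	Side chain interaction parameter	selected
KRIW790102	Fraction of site occupied by water	selected
KRIW790103	Side chain volume	selected
LAWE840101	Transfer free energy, CHP/water	selected
OOBM850105	Optimized side chain interaction parameter	selected
WARP780101	Average interactions per side chain atom	rejected
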