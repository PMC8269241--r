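category	pattern	priority
metal_resistance	copper resistance	10
metal_resistance	copa	10
metal_resistance	copb	10
metal_resistance	copper	11
metal_resistance	cobalt	11
metal_resistance	zinc transport	11
metal_resistance	cadmium	11
metal_resistance	mercur	11
metal_resistance	arsenic	11
metal_resistance	arsenate	11
metal_resistance	czc	11
antibiotic_resistance	beta-lactamase	20
antibiotic_resistance	lactamase	20
antibiotic_resistance	acrb/acrd/acrf	20
antibiotic_resistance	streptomycin adenylyltransferase	20
antibiotic_resistance	spectinomycin	21
antibiotic_resistance	fosfomycin	21
antibiotic_resistance	multidrug efflux	21
antibiotic_resistance	aminoglycoside	21
toxin_antitoxin	antitoxin	30
toxin_antitoxin	toxin-antitoxin	30
toxin_antitoxin	rele	31
toxin_antitoxin	mazf	31
toxin_antitoxin	vapc	31
toxin_antitoxin	higb	31
phage_hallmark	capsid	40
phage_hallmark	terminase	40
phage_hallmark	portal	40
phage_hallmark	tail	40
phage_hallmark	baseplate	40
phage_hallmark	integrase	40
phage_hallmark	holin	40
phage_hallmark	phage	41
metabolism	dehydrogenase	50
metabolism	kinase	50
metabolism	synthase	50
metabolism	reductase	50
metabolism	transferase	51
metabolism	hydrolase	51
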