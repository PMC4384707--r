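category	subcategory
DNA damage and repair	damage response
DNA damage and repair	repair
chromatin organization	chromatin organization
gene expression integrity	transcription fidelity
gene expression integrity	RNA processing
cellular integrity	membrane and cytoskeleton
cellular integrity	proteostasis
cell cycle and differentiation	cell cycle
cell cycle and differentiation	differentiation
cell communication	signal transduction
cell communication	intercellular signaling
metabolism	energy metabolism
metabolism	lipid metabolism
metabolism	transport
stress response	immune response
stress response	other stress
organismic regulation	behavior
organismic regulation	ontogenesis
organismic regulation	reproduction
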