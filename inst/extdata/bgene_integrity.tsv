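gene_name	protein_symbol	integrity	category
apoptosis regulator Bcl-2-like	BCL2	100	B-related protein
coxsackievirus and adenovirus receptor-like	CXAR	100	B-related protein
spindle and kinetochore-associated protein 1-like	SKA1	100	B-related protein
kinesin-like protein KIF11-like	KIF11	96.13	B-related protein
zinc finger protein 771-like	ZNF71	89.37	B-related protein
serine/threonine-protein kinase RIO3-like	RIOK3	81.57	B-related protein
ATP-binding cassette sub-family A member 1-like	ABCA1	80.25	B-related protein
aurora kinase A-B-like	AURKA	77.16	B-related protein
centromere-associated protein E-like	CENPE	73.92	B-related protein
zinc finger protein 836-like	ZN836	64.52	B-related protein
histone-lysine N-methyltransferase MLL3-like	KMT2C	56.16	B-related protein
butyrophilin subfamily 2 member A1-like	BT2A1	100	Other protein
butyrophilin-like protein 2-like	BTNL2	100	Other protein
myosin-10-like	MYH10	100	Other protein
polymeric immunoglobulin receptor-like	PIGR	100	Other protein
serine protease 23-like	PRS23	100	Other protein
peptide chain release factor 1-like, mitochondrial-like	RF1ML	100	Other protein
VIP peptides-like	VIP	100	Other protein
zinc finger protein 879-like	ZN879	100	Other protein
ATP-dependent RNA helicase DDX51-like	DDX51	92.22	Other protein
CD209 antigen-like	CD209	90.13	Other protein
protocadherin-10-like	PCD10	89.58	Other protein
heterogeneous nuclear ribonucleoprotein Q-like	HNRPQ	79.90	Other protein
leucine-rich repeat-containing protein 30-like	LRC30	71.93	Other protein
synaptonemal complex protein 2-like	SYCP2	70.97	Other protein
extracellular calcium-sensing receptor-like	CASR	69.46	Other protein
protein NLRC3-like	NLRC3	68.24	Other protein
guanine nucleotide-binding protein G	GNAI1	67.52	Other protein
vascular cell adhesion protein 1-like	VCAM1	65.79	Other protein
torsin-1A-interacting protein 2-like	ELOF1	64.25	Other protein
zinc finger protein 782-like	ZN782	63.42	Other protein
zinc finger protein 678-like	ZN678	63.01	Other protein
V-set domain-containing T-cell activation inhibitor 1-like	VTCN1	63.00	Other protein
poly [ADP-ribose] polymerase 14-like	PAR14	61.53	Other protein
DNA-directed RNA polymerase E subunit 1-like	RPA49	61.01	Other protein
endonuclease domain-containing 1 protein-like	ENDD1	58.21	Other protein
SAM domain and HD domain-containing protein 1-like	ESPL1	57.51	Other protein
targeting protein for Xklp2-A-like	TPX2	52.30	Other protein
interferon-induced very large GTPase 1-like	GVIN1	51.55	Other protein
sterile alpha motif domain-containing protein 12-like	SAM12	51.27	Other protein
xylulose kinase-like	XYLB	50.52	Other protein
glucose-6-phosphate 1-dehydrogenase-like	G6PD	50.43	Other protein
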