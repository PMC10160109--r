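# Default functional-group catalog (version 1): 33 common functional groups
# expressed in the SMARTS subset supported by the package matcher.
# Columns: name <TAB> SMARTS <TAB> graft SMILES (optional; first atom is the
# attachment atom, empty when the group is not a terminal substituent).
hydroxyl	[O;H1;D1;!$(O-C=O);!$(O-S=O)]	O
carboxylic_acid	[C;D3](=O)[O;H1]	C(=O)O
ester	[C;D3;!R](=O)[O;D2][#6]
amide	[C;D3](=O)[N;!$(N-C=N)]	C(N)=O
ketone	[#6][C;D3;!R](=O)[#6]
aldehyde	[C;H1;D2]=O	C=O
ether	[O;D2;!R]([C;!$(C=O)])[C;!$(C=O)]
primary_amine	[N;H2;D1;+0;!$(N-C=O);!$(N-C=N);!$(N-S=O)]	N
secondary_amine	[N;H1;D2;+0;!$(N-C=O);!$(N-C=N);!$(N-S=O)]
tertiary_amine	[N;H0;D3;+0;!R;!$(N-C=O);!$(N-C=N);!$(N-S=O);!$(N=C)]	N(C)C
nitro	[N;+1](=O)[O;-1]	[N+](=O)[O-]
nitrile	[C;D2](#N)[#6]	C#N
fluoro	[F]	F
chloro	[Cl]	Cl
bromo	[Br]	Br
iodo	[I]	I
trifluoromethyl	[C;D4](F)(F)F	C(F)(F)F
methyl	[C;H3;D1;!$(C-[!#6])]	C
methoxy	[C;H3;D1][O;D2][#6]	OC
thiol	[S;H1;D1]	S
thioether	[S;D2;!R]([#6])[#6]
sulfoxide	[S;D3](=O)([#6])[#6]
sulfone	[S;D4](=O)(=O)([#6])[#6]
sulfonamide	[S;D4](=O)(=O)[N]	S(N)(=O)=O
sulfonic_acid	[S;D4](=O)(=O)[O;H1]	S(O)(=O)=O
phosphoryl	[P;D4]=O
urea	[N][C;D3](=O)[N]
carbamate	[N][C;D3](=O)[O;D2][#6]
guanidine	[N][C;D3](=[N])[N]
imine	[C;D2,D3;!R]=[N;!R;!$(N-N)]
azide	[N;D2]=[N;+1]=[N;-1]	N=[N+]=[N-]
alkyne	[C;D2]#[C;D2]
alkene	[C;!R]=[C;!R]
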