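# Default shape-string torsion-region table (synthetic approximation).
# The published shape-string assignment server does not print its
# phi/psi boundaries; this partition of the Ramachandran plane is the
# package's own documented approximation, shipped as data so users can
# substitute their own. Rows are matched first-to-last; bounds are
# lower-inclusive, upper-exclusive on angles normalized to [-180,180).
# glycine_only rows apply only to glycine and are checked before the
# base rows.
letter	phi_lo	phi_hi	psi_lo	psi_hi	glycine_only
G	0	180	-100	100	TRUE
S	-180	-100	100	180	FALSE
S	-180	-100	-180	-150	FALSE
R	-100	0	100	180	FALSE
R	-100	0	-180	-150	FALSE
U	-180	-100	45	100	FALSE
V	-100	0	45	100	FALSE
K	-180	0	10	45	FALSE
A	-180	0	-110	10	FALSE
T	-180	180	-180	180	FALSE
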