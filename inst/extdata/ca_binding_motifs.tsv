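# Calcium-binding motif signatures in PROSITE pattern syntax.
# One "name<TAB>pattern" per line; "#" starts a comment.
#
# The PERCAL block is the stringency ladder used when characterising
# glycine/aspartate-rich insertions in bacterial animal-peroxidase-like
# (ANP-like) domains, from the relaxed discovery motif down to the
# strictest variant, plus the database-screen variants that restrict the
# ninth position. The remaining entries are classic calcium-binding
# signatures kept for comparison scans.
PERCAL	G-x-D-G-x(2)-[GN]-[TN]-x-D-D
relaxed_gxd_dede	G-x-D-x(6)-[DE]-[DE]
gxd_dd	G-x-D-x(6)-D-D
gxdg_dd	G-x-D-G-x(5)-D-D
gxdg_dede	G-x-D-G-x(5)-[DE]-[DE]
gxdg_dde	G-x-D-G-x(5)-D-[DE]
percal_at9	G-x-D-G-x(2)-[GN]-[TN]-[AT]-D-D
percal_gt_at9	G-x-D-G-x(2)-G-[TN]-[AT]-D-D
strict_gtadd	G-x-D-G-x(2)-G-T-A-D-D
notG4_dd	G-x-D-{G}-x(5)-D-D
notG4_dede	G-x-D-{G}-x(5)-[DE]-[DE]
percal_aet9	G-x-D-G-x(2)-[GN]-[TN]-[AET]-D-D
percal_d9	G-x-D-G-x(2)-[GN]-[TN]-D-D-D
percal_adet9	G-x-D-G-x(2)-[GN]-[TN]-[ADET]-D-D
HTCaB	D-x-[LI]-x(4)-G-x-D-x-[LI]-x-G-G-x(3)-D
EF_hand	D-{W}-[DNS]-{ILVFYW}-[DENSTG]-[DNQGHRK]-{GP}-[LIVMC]-[DENQSTAGC]-x(2)-[DE]-[LIVMFYW]
Ca_EGF	[DEQN]-x-[DEQN](2)-C-x(3,14)-C-x(3,7)-C-x-[DN]-x(4)-[FY]-x-C
cadherin	[LIV]-x-[LIV]-x-D-x-N-D-[NH]-x-P
excalibur	D-x-D-x-D-G-x(2)-C-E
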