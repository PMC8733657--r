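# Human fasted gastrointestinal segments for the compartmental
# absorption-transit model: serial first-order transit, dissolution,
# passive permeation and saturable PEPT1 uptake.
# pept1_mg is the absolute segmental PEPT1 protein content; pept1_scale
# is the calibrated global transporter capacity multiplier (see
# calibrate_transporter_scale); fluid volume = fluid_fraction * pi r^2 L.
km_mg_l=860.31
vmax_ug_s_mg=0.0025
pept1_scale=768
fluid_fraction=0.4
segment.stomach.transit_h=0.25
segment.stomach.radius_cm=1.75
segment.stomach.length_cm=12.0
segment.stomach.pept1_mg=0
segment.stomach.passive_scale=0
segment.duodenum.transit_h=0.26
segment.duodenum.radius_cm=1.6
segment.duodenum.length_cm=15
segment.duodenum.pept1_mg=16.28
segment.duodenum.passive_scale=1.0
segment.jejunum1.transit_h=0.93
segment.jejunum1.radius_cm=1.45
segment.jejunum1.length_cm=60
segment.jejunum1.pept1_mg=87.84
segment.jejunum1.passive_scale=1.0
segment.jejunum2.transit_h=0.74
segment.jejunum2.radius_cm=1.3
segment.jejunum2.length_cm=60
segment.jejunum2.pept1_mg=73.93
segment.jejunum2.passive_scale=1.0
segment.ileum1.transit_h=0.58
segment.ileum1.radius_cm=1.2
segment.ileum1.length_cm=40
segment.ileum1.pept1_mg=78.61
segment.ileum1.passive_scale=1.0
segment.ileum2.transit_h=0.42
segment.ileum2.radius_cm=1.0
segment.ileum2.length_cm=40
segment.ileum2.pept1_mg=63.41
segment.ileum2.passive_scale=1.0
segment.ileum3.transit_h=0.29
segment.ileum3.radius_cm=0.9
segment.ileum3.length_cm=40
segment.ileum3.pept1_mg=49.29
segment.ileum3.passive_scale=1.0
segment.caecum.transit_h=4.5
segment.caecum.radius_cm=3.5
segment.caecum.length_cm=14
segment.caecum.pept1_mg=0
segment.caecum.passive_scale=0.18
segment.colon.transit_h=13.5
segment.colon.radius_cm=2.5
segment.colon.length_cm=29
segment.colon.pept1_mg=0
segment.colon.passive_scale=0.18
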