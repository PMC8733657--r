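# Rat physiology: compartment volumes (mL), blood flows (mL/s), Kp.
# The liver flow is the total hepatic outflow (hepatic artery + spleen + gut).
species=rat
body_weight_kg=0.31
haematocrit=0.45
cardiac_output_ml_s=0.9389
arterial_volume_ml=6.944
venous_volume_ml=14.012
gut_flow_ml_s=0.14689
tissue.lung.volume_ml=2.604
tissue.lung.flow_ml_s=0.9389
tissue.lung.kp=0.52
tissue.adipose.volume_ml=12.4
tissue.adipose.flow_ml_s=0.00784
tissue.adipose.kp=0.1
tissue.muscle.volume_ml=151.28
tissue.muscle.flow_ml_s=0.14695
tissue.muscle.kp=0.25
tissue.liver.volume_ml=12.772
tissue.liver.flow_ml_s=0.23111
tissue.liver.kp=0.81
tissue.spleen.volume_ml=0.744
tissue.spleen.flow_ml_s=0.01175
tissue.spleen.kp=0.41
tissue.heart.volume_ml=1.488
tissue.heart.flow_ml_s=0.07638
tissue.heart.kp=0.23
tissue.brain.volume_ml=1.53402
tissue.brain.flow_ml_s=0.02554
tissue.brain.kp=0.11
tissue.kidney.volume_ml=4.588
tissue.kidney.flow_ml_s=0.18019
tissue.kidney.kp=6.87
tissue.skin.volume_ml=49.6
tissue.skin.flow_ml_s=0.11361
tissue.skin.kp=0.89
tissue.repro_organ.volume_ml=3.1
tissue.repro_organ.flow_ml_s=0.00979
tissue.repro_organ.kp=0.5
tissue.red_marrow.volume_ml=2.31146
tissue.red_marrow.flow_ml_s=0.03568
tissue.red_marrow.kp=0.47
tissue.yellow_marrow.volume_ml=5.14347
tissue.yellow_marrow.flow_ml_s=0.00794
tissue.yellow_marrow.kp=0.25
tissue.rest_of_body.volume_ml=30.282
tissue.rest_of_body.flow_ml_s=0.10386
tissue.rest_of_body.kp=0.5
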