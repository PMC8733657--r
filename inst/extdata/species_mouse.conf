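# Mouse physiology: compartment volumes (mL), blood flows (mL/s),
# tissue:plasma partition coefficients (Kp).
# The liver flow is the total hepatic outflow (hepatic artery + spleen + gut).
species=mouse
body_weight_kg=0.025
haematocrit=0.45
cardiac_output_ml_s=0.11347
arterial_volume_ml=0.57
venous_volume_ml=1.13
gut_flow_ml_s=0.02498
tissue.lung.volume_ml=0.15833
tissue.lung.flow_ml_s=0.11347
tissue.lung.kp=0.52
tissue.adipose.volume_ml=1.91048
tissue.adipose.flow_ml_s=0.00127
tissue.adipose.kp=0.1
tissue.muscle.volume_ml=9.2219
tissue.muscle.flow_ml_s=0.01517
tissue.muscle.kp=0.25
tissue.liver.volume_ml=1.66355
tissue.liver.flow_ml_s=0.03352
tissue.liver.kp=0.81
tissue.spleen.volume_ml=0.10081
tissue.spleen.flow_ml_s=0.0015
tissue.spleen.kp=0.41
tissue.heart.volume_ml=0.10922
tissue.heart.flow_ml_s=0.00467
tissue.heart.kp=0.23
tissue.brain.volume_ml=0.41647
tissue.brain.flow_ml_s=0.00759
tissue.brain.kp=0.11
tissue.kidney.volume_ml=0.38929
tissue.kidney.flow_ml_s=0.0213
tissue.kidney.kp=6.87
tissue.skin.volume_ml=3.51582
tissue.skin.flow_ml_s=0.01009
tissue.skin.kp=0.89
tissue.repro_organ.volume_ml=0.148
tissue.repro_organ.flow_ml_s=0.00049
tissue.repro_organ.kp=0.5
tissue.red_marrow.volume_ml=0.83204
tissue.red_marrow.flow_ml_s=0.01355
tissue.red_marrow.kp=0.47
tissue.yellow_marrow.volume_ml=0.52449
tissue.yellow_marrow.flow_ml_s=0.00085
tissue.yellow_marrow.kp=0.25
tissue.rest_of_body.volume_ml=1.3735
tissue.rest_of_body.flow_ml_s=0.00497
tissue.rest_of_body.kp=0.5
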