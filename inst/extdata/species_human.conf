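# Human physiology: compartment volumes (mL), blood flows (mL/s), Kp.
# The liver flow is the total hepatic outflow (hepatic artery + spleen + gut).
species=human
body_weight_kg=75.1
haematocrit=0.45
cardiac_output_ml_s=98.1779
arterial_volume_ml=2148.17
venous_volume_ml=4296.34
gut_flow_ml_s=12.263
tissue.lung.volume_ml=1125.5
tissue.lung.flow_ml_s=98.1779
tissue.lung.kp=0.52
tissue.adipose.volume_ml=24307.3
tissue.adipose.flow_ml_s=8.09433
tissue.adipose.kp=0.1
tissue.muscle.volume_ml=25174.7
tissue.muscle.flow_ml_s=12.5874
tissue.muscle.kp=0.25
tissue.liver.volume_ml=1590.1
tissue.liver.flow_ml_s=24.3444
tissue.liver.kp=0.81
tissue.spleen.volume_ml=169.973
tissue.spleen.flow_ml_s=2.83294
tissue.spleen.kp=0.41
tissue.heart.volume_ml=337.26
tissue.heart.flow_ml_s=4.10344
tissue.heart.kp=0.23
tissue.brain.volume_ml=1493.16
tissue.brain.flow_ml_s=12.6919
tissue.brain.kp=0.11
tissue.kidney.volume_ml=360.411
tissue.kidney.flow_ml_s=22.1051
tissue.kidney.kp=6.87
tissue.skin.volume_ml=2831.73
tissue.skin.flow_ml_s=5.66346
tissue.skin.kp=0.89
tissue.repro_organ.volume_ml=50.6174
tissue.repro_organ.flow_ml_s=0.17716
tissue.repro_organ.kp=0.5
tissue.red_marrow.volume_ml=1106.48
tissue.red_marrow.flow_ml_s=5.53242
tissue.red_marrow.kp=0.47
tissue.yellow_marrow.volume_ml=3075.64
tissue.yellow_marrow.flow_ml_s=1.53782
tissue.yellow_marrow.kp=0.25
tissue.rest_of_body.volume_ml=2681.07
tissue.rest_of_body.flow_ml_s=1.34054
tissue.rest_of_body.kp=0.5
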