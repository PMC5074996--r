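# Imaging protocol for the laboratory micro-CT / angiography setup:
# liquid-metal-jet source, flat-panel detector, ventilated mouse at peak
# inspiration.
detector_pixel_mm: 0.194
source_to_isocenter_mm: 374
source_to_detector_mm: 3315
n_projections: 800
exposure_s: 0.015
kerma_rate_mgy_s: 5.01
ld50_gy: 7
insp_ms: 300
exp_ms: 300
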