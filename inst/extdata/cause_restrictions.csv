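cause_id,sex,age_min,age_max
maternal_hemorrhage,female,12,49
maternal_sepsis,female,12,49
maternal_hypertensive,female,12,49
maternal_other,female,12,49
cervical_cancer,female,,
breast_cancer,female,,
uterine_cancer,female,,
prostate_cancer,male,,
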