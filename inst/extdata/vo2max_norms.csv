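# Normative maximal oxygen uptake (VO2max, ml O2 . kg^-1 . min^-1) by gender,
# decadal age bracket and cardiorespiratory fitness category.
# EXTERNAL REFERENCE DATA: values adapted from standard normative
# cardiorespiratory-fitness classifications (ACSM-style percentile tables);
# they are population reference values, not measurements from any single
# study. Prefer a measured VO2max (subject_profile(vo2max = ...)) when one
# is available. Ages outside 20-89 are clamped to the nearest bracket.
gender,age_lo,age_hi,category,vo2max_ml_kg_min
male,20,29,poor,32
male,20,29,fair,37
male,20,29,good,44
male,20,29,excellent,51
male,20,29,superior,56
male,30,39,poor,30
male,30,39,fair,35
male,30,39,good,40
male,30,39,excellent,47
male,30,39,superior,52
male,40,49,poor,27
male,40,49,fair,31
male,40,49,good,38
male,40,49,excellent,44
male,40,49,superior,50
male,50,59,poor,24
male,50,59,fair,28
male,50,59,good,34
male,50,59,excellent,40
male,50,59,superior,46
male,60,69,poor,21
male,60,69,fair,25
male,60,69,good,31
male,60,69,excellent,36
male,60,69,superior,42
male,70,79,poor,18
male,70,79,fair,22
male,70,79,good,27
male,70,79,excellent,32
male,70,79,superior,38
male,80,89,poor,16
male,80,89,fair,19
male,80,89,good,24
male,80,89,excellent,28
male,80,89,superior,34
female,20,29,poor,27
female,20,29,fair,32
female,20,29,good,38
female,20,29,excellent,44
female,20,29,superior,49
female,30,39,poor,25
female,30,39,fair,29
female,30,39,good,34
female,30,39,excellent,40
female,30,39,superior,45
female,40,49,poor,22
female,40,49,fair,26
female,40,49,good,31
female,40,49,excellent,37
female,40,49,superior,42
female,50,59,poor,19
female,50,59,fair,23
female,50,59,good,28
female,50,59,excellent,33
female,50,59,superior,38
female,60,69,poor,17
female,60,69,fair,20
female,60,69,good,25
female,60,69,excellent,30
female,60,69,superior,35
female,70,79,poor,15
female,70,79,fair,18
female,70,79,good,22
female,70,79,excellent,26
female,70,79,superior,31
female,80,89,poor,13
female,80,89,fair,16
female,80,89,good,19
female,80,89,excellent,23
female,80,89,superior,27
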