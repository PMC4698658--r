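# Normalization of clinical sample-type labels to the package vocabulary
# {normal, primary, metastatic, blood}. Editable: ship your own map and pass
# it to load_cohort(sample_type_map = ...). Matching is case-insensitive.
"Solid Tissue Normal": normal
"Normal": normal
"Primary Tumor": primary
"Primary solid Tumor": primary
"Primary": primary
"Metastatic": metastatic
"Additional Metastatic": metastatic
"Primary Blood Derived Cancer - Peripheral Blood": blood
"Blood Derived Normal": blood
"Blood": blood
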