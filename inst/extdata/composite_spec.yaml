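# Facet composite specification (synthetic item names).
# Each facet composite is the mean of its items at the given timepoint.
# year2 item lists are subsets of baseline for intent (substance-gating items
# not re-collected) and fdhx (family-history items excluded at wave 2); the
# access item set is identical at both waves.
winsor_z: 3.5
facets:
  intent:
    baseline_items: [intent_01, intent_02, intent_03, intent_04, intent_05,
                     intent_06, intent_07, intent_08, intent_09, intent_10]
    year2_items: [intent_01, intent_02, intent_03, intent_04, intent_05,
                  intent_06, intent_07, intent_08]
  access:
    baseline_items: [access_01, access_02, access_03, access_04, access_05,
                     access_06, access_07, access_08, access_09, access_10]
    year2_items: [access_01, access_02, access_03, access_04, access_05,
                  access_06, access_07, access_08, access_09, access_10]
  fdhx:
    baseline_items: [fdhx_01, fdhx_02, fdhx_03, fdhx_04, fdhx_05,
                     fdhx_06, fdhx_07, fdhx_08, fdhx_09, fdhx_10]
    year2_items: [fdhx_01, fdhx_02, fdhx_03, fdhx_04, fdhx_05,
                  fdhx_06, fdhx_07, fdhx_08]
upps_items: [upps_01, upps_02, upps_03, upps_04, upps_05, upps_06, upps_07,
             upps_08, upps_09, upps_10, upps_11, upps_12, upps_13, upps_14,
             upps_15, upps_16, upps_17, upps_18, upps_19, upps_20]
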