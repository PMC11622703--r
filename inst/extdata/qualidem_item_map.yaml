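# QUALIDEM item-to-subscale map (editable).
# Subscales: A care relationship, B positive affect, C negative affect,
# D restless tense behaviour, E positive self-image, F social relations,
# G social isolation, H feeling at home, I occupation, J other.
# Negative-worded subscales (C, D, G) are reverse-scored before summing.
items:
  - {item: item_01, subscale: A, reverse: false, max_rating: 3}
  - {item: item_02, subscale: A, reverse: false, max_rating: 3}
  - {item: item_03, subscale: A, reverse: false, max_rating: 3}
  - {item: item_04, subscale: A, reverse: false, max_rating: 3}
  - {item: item_05, subscale: A, reverse: false, max_rating: 3}
  - {item: item_06, subscale: A, reverse: false, max_rating: 3}
  - {item: item_07, subscale: A, reverse: false, max_rating: 3}
  - {item: item_08, subscale: B, reverse: false, max_rating: 3}
  - {item: item_09, subscale: B, reverse: false, max_rating: 3}
  - {item: item_10, subscale: B, reverse: false, max_rating: 3}
  - {item: item_11, subscale: B, reverse: false, max_rating: 3}
  - {item: item_12, subscale: B, reverse: false, max_rating: 3}
  - {item: item_13, subscale: B, reverse: false, max_rating: 3}
  - {item: item_14, subscale: C, reverse: true, max_rating: 3}
  - {item: item_15, subscale: C, reverse: true, max_rating: 3}
  - {item: item_16, subscale: C, reverse: true, max_rating: 3}
  - {item: item_17, subscale: D, reverse: true, max_rating: 3}
  - {item: item_18, subscale: D, reverse: true, max_rating: 3}
  - {item: item_19, subscale: D, reverse: true, max_rating: 3}
  - {item: item_20, subscale: E, reverse: false, max_rating: 3}
  - {item: item_21, subscale: E, reverse: false, max_rating: 3}
  - {item: item_22, subscale: E, reverse: false, max_rating: 3}
  - {item: item_23, subscale: F, reverse: false, max_rating: 3}
  - {item: item_24, subscale: F, reverse: false, max_rating: 3}
  - {item: item_25, subscale: F, reverse: false, max_rating: 3}
  - {item: item_26, subscale: F, reverse: false, max_rating: 3}
  - {item: item_27, subscale: F, reverse: false, max_rating: 3}
  - {item: item_28, subscale: F, reverse: false, max_rating: 3}
  - {item: item_29, subscale: G, reverse: true, max_rating: 3}
  - {item: item_30, subscale: G, reverse: true, max_rating: 3}
  - {item: item_31, subscale: G, reverse: true, max_rating: 3}
  - {item: item_32, subscale: H, reverse: false, max_rating: 3}
  - {item: item_33, subscale: H, reverse: false, max_rating: 3}
  - {item: item_34, subscale: H, reverse: false, max_rating: 3}
  - {item: item_35, subscale: H, reverse: false, max_rating: 3}
  - {item: item_36, subscale: I, reverse: false, max_rating: 3}
  - {item: item_37, subscale: I, reverse: false, max_rating: 3}
  - {item: item_38, subscale: J, reverse: false, max_rating: 3}
  - {item: item_39, subscale: J, reverse: false, max_rating: 3}
  - {item: item_40, subscale: J, reverse: false, max_rating: 3}
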