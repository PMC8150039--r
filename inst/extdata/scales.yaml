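# Instrument layout for the synthetic Dutch/Flemish gamer survey emulated by this
# package. Items are 1-5 Likert. "reverse" items are worded against the scale
# direction and contribute 6 - response to the mean score. "core" items directly
# assess negative consequences (interference) rather than engagement.
#
# The item texts of the original instruments are not reproduced; ids carry the
# criterion each item stands for.

pages:
  - demographics
  - vat
  - mhi
  - cvat2
  - motivations
  - adm
  - icd
  - needs
  - swl
  - odba
  - gko

attention_checks:
  check_1: cvat2      # page on which each check is embedded
  check_2: swl

scales:
  vat:
    construct: dysregulation
    items: [vat_1, vat_2, vat_3, vat_4, vat_5, vat_6, vat_7, vat_8,
            vat_9, vat_10, vat_11, vat_12, vat_13, vat_14]
    # 1-4 loss of control, 5-8 conflict, 9-11 preoccupation/salience,
    # 12-13 coping/mood modification, 14 withdrawal
    reverse: []
    core: [vat_1, vat_2, vat_3, vat_4, vat_5, vat_6, vat_7, vat_8]
  cvat2:
    construct: dysregulation
    items: [cvat2_1, cvat2_2, cvat2_3, cvat2_4, cvat2_5, cvat2_6,
            cvat2_7, cvat2_8, cvat2_9, cvat2_10, cvat2_11]
    # 1 tolerance, 2 withdrawal, 3 loss of control, 4 preoccupation,
    # 5 mood modification/escapism, 6 loss of interests, 7 lying/deception,
    # 8 continuation despite problems, 9 problems (work/social),
    # 10 craving, 11 problems (health)
    reverse: []
    core: [cvat2_2, cvat2_3, cvat2_6, cvat2_8, cvat2_9, cvat2_10, cvat2_11]
  icd:
    construct: dysregulation
    items: [icd_1, icd_2, icd_3, icd_4]
    # 1 loss of control, 2 loss of interests/priority, 3 continuation despite
    # problems, 4 problems persist > 1 year
    reverse: []
    core: [icd_1, icd_2, icd_3, icd_4]
  odba:
    construct: dysregulation
    items: [odba_1, odba_2, odba_3, odba_4]
    # 3 "gaming does not lead to problems" and 4 "time spent is a conscious
    # choice" are negatively phrased
    reverse: [odba_3, odba_4]
    core: [odba_1, odba_2, odba_3]
  gko:
    construct: dysregulation
    items: [gko_1, gko_2, gko_3, gko_4, gko_5]
    reverse: []
    core: [gko_1, gko_2, gko_3, gko_4, gko_5]
  mhi:
    construct: general_mental_health
    items: [mhi_1, mhi_2, mhi_3, mhi_4, mhi_5]
    # 1-3 are distress-worded (nervousness, low mood, downhearted) and are
    # reverse-coded so that higher scores mean better mental health; 4-5 are
    # the positively-worded (happy/calm) items
    reverse: [mhi_1, mhi_2, mhi_3]
    core: [mhi_1, mhi_2, mhi_3, mhi_4, mhi_5]
  adm:
    construct: depressive_mood
    items: [adm_1, adm_2, adm_3, adm_4, adm_5, adm_6]
    # tiredness, sleep problems, sadness, hopelessness, nervousness, anxiety
    reverse: []
    core: [adm_1, adm_2, adm_3, adm_4, adm_5, adm_6]
  swl:
    construct: life_satisfaction
    items: [swl_1, swl_2, swl_3, swl_4, swl_5]
    reverse: []
    core: [swl_1, swl_2, swl_3, swl_4, swl_5]

# The nine justifiable operationalizations of dysregulated-gaming severity.
predictors:
  vat:        {scale: vat,   subset: all}
  vat_core:   {scale: vat,   subset: core}
  cvat2_9item:  {scale: cvat2, subset: [cvat2_1, cvat2_2, cvat2_3, cvat2_4, cvat2_5,
                                        cvat2_6, cvat2_7, cvat2_8, cvat2_9]}
  cvat2_11item: {scale: cvat2, subset: all}
  cvat2_core: {scale: cvat2, subset: core}
  icd11:      {scale: icd,   subset: all}
  odba:       {scale: odba,  subset: all}
  gko:        {scale: gko,   subset: all}
  cvat3:      {scale: [cvat2, icd], subset: all}

outcomes:
  general_mental_health:    {scale: mhi, reversed: no}
  absence_depressive_mood:  {scale: adm, reversed: yes}
  life_satisfaction:        {scale: swl, reversed: no}
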