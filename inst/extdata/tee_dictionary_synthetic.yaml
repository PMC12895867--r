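# Synthetic illustrative thromboembolic-event PT dictionary.
# This is NOT a licensed MedDRA SMQ export: it is a small hand-written
# stand-in covering common thromboembolic Preferred Term strings so the
# pipeline can be exercised and tested. Real analyses must supply PT
# lists derived from the user's own MedDRA licence.
smq_id: "synthetic-example"
categories:
  VTE:
    - PULMONARY EMBOLISM
    - DEEP VEIN THROMBOSIS
    - PELVIC VENOUS THROMBOSIS
    - PORTAL VEIN THROMBOSIS
    - JUGULAR VEIN THROMBOSIS
  ATE:
    - MYOCARDIAL INFARCTION
    - ACUTE MYOCARDIAL INFARCTION
    - CEREBRAL INFARCTION
    - ISCHAEMIC STROKE
    - CEREBRAL ARTERY EMBOLISM
    - PERIPHERAL ARTERY THROMBOSIS
    - MESENTERIC ARTERY THROMBOSIS
  unspecified_mixed:
    - THROMBOSIS
    - EMBOLISM
    - THROMBOEMBOLIC EVENT
subtypes:
  PE:
    - PULMONARY EMBOLISM
  MI:
    - MYOCARDIAL INFARCTION
    - ACUTE MYOCARDIAL INFARCTION
  cerebral_ATE:
    - CEREBRAL INFARCTION
    - ISCHAEMIC STROKE
    - CEREBRAL ARTERY EMBOLISM
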