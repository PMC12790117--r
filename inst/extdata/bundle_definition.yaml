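# Default tiered respiratory-care resource bundle definition.
# Tier membership is configuration, not code: the scoring engine is
# item-list agnostic. This default transcription reflects the tiered
# bundle concept (basic oxygen delivery -> invasive ventilation support);
# sites are surveyed on the atomic items only, composites are derived.
tiers:
  basic:
    - oxygen_source
    - pulse_oximetry
    - nasal_cannula
    - simple_face_mask
    - suction
    - nebulizer
  intermediate:
    - bag_valve_mask
    - oropharyngeal_airway
    - nonrebreather_mask
    - humidified_oxygen
    - chest_xray
  advanced:
    - hfnc
    - cpap
    - bipap
    - intubation_supplies
    - sedation
  expert:
    - mechanical_ventilator
    - blood_gas_analyzer
    - capnography
    - tracheostomy_supplies
composites:
  pulse_oximetry:
    rule: any
    of: [portable_oximetry, continuous_oximetry]
  intubation_supplies:
    rule: all
    of: [laryngoscopes, endotracheal_tubes]
  sedation:
    rule: any
    of: [iv_opioids, benzodiazepines, propofol, ketamine]
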