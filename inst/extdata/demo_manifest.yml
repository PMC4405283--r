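# Synthetic manifest accompanying the demo logger fragment: two familiar
# animals (raw IDs 1, 2) and an unfamiliar animal (3) introduced at the
# time of the first recorded encounter.
triad_id: DEMO
animals:
  "1": 1
  "2": 2
  "3": 3
introduction: "09/03/2009 18:49:34"
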