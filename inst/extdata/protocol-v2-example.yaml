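# Example protocol configuration for load_protocol().
#
# Only version_id is required; everything else overrides the built-in
# defaults for that version. Question banks may be replaced wholesale
# via a `questions` table (columns: id, instrument, type, lo, hi, text,
# task_kind); item texts are customizable, answer domains are validated
# (vas 0-10, stanford_sleepiness 1-7, 24 diary items, no free text).
version_id: v2.0
home_nights: 14
afternoon_default_time: "15:00"
features:
  auto_session_flow: true
  kiosk_mode: true
  interaction_logging: true
  store_and_forward: true
sessions:
  - kind: on_waking
    offset_min: 30      # fixed by the protocol: wake anchor + 30 min
    window_min: 180     # also truncated by the first-medication anchor
  - kind: after_medications
    offset_min: 60      # first dose + 60 min
    window_min: 180
  - kind: afternoon
    window_min: 240     # truncated by the bedtime anchor
  - kind: evening
    window_min: 60
  - kind: nap
    window_min: 60
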