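# Demo workflow in the style of a wheel-running experiment: behaviorally
# triggered events of varying length, small bouts aggregated, 20-s baseline.
seed: 7
simulate:
  scenario: custom
  name: wheel_session
  duration: 600
  rate: 20
  noise_sd: 0.01
  events:
    - {onset: 60,  length: 8}
    - {onset: 75,  length: 20}
    - {onset: 180, length: 5}
    - {onset: 188, length: 12}
    - {onset: 320, length: 30}
    - {onset: 470, length: 15}
events:
  - name: running
    dataset: wheel_session
    channel: fluorescence
    detector: {type: binary, variable: ttl}
    filters:
      - {kind: aggregate, gap: 10}
      - {kind: drop_short, min_length: 10}
    intervals:
      - {name: baseline, reference: event_start_no_overlap, start_off: -20, end_off: 0}
      - {name: signal, reference: event_signal}
    normalizations:
      - {scheme: dff, reference: baseline}
analysis:
  - {series: running, product: mean_trace, value: dff, band: se, multiplier: 1}
  - {series: running, product: heatmap, value: dff, sort: order}
export:
  event_tables: {layout: long}
  session: session.json
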