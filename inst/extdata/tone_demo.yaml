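# Demo workflow: synthetic 900-s tone session, TTL-triggered events,
# 3-s baseline / 5-s post window, dF/F normalization, ETA products.
seed: 20
simulate:
  scenario: tone
  name: tone_session
  glitches: {channel: ttl, count: 20}
events:
  - name: tones
    dataset: tone_session
    channel: fluorescence
    detector: {type: binary, variable: ttl}
    filters:
      - {kind: drop_short, min_length: 1}
    intervals:
      - {name: baseline, reference: event_start, start_off: -3, end_off: 0}
      - {name: signal, reference: event_signal}
      - {name: post, reference: event_end, start_off: 0, end_off: 5}
    normalizations:
      - {scheme: dff, reference: baseline}
      - {scheme: zscore, reference: baseline}
analysis:
  - {series: tones, product: mean_trace, value: dff, band: se, multiplier: 1}
  - {series: tones, product: heatmap, value: dff, sort: order}
  - {series: tones, product: interval_summaries, stat: mean, value: dff}
export:
  event_tables: {layout: wide, align_by: time, value: dff}
  session: session.json
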