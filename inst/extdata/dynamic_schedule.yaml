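# Dynamic (daylight-simulating) lighting program: photopic lux at eye
# level, correlated colour temperature (K), luminaire output (%).
schedule:
  - {start: "07:00", end: "08:00", lux: 300, cct: 3350, output_pct: 90}
  - {start: "08:00", end: "08:30", lux: 550, cct: 4000, output_pct: 100}
  - {start: "08:30", end: "09:00", lux: 550, cct: 5200, output_pct: 100}
  - {start: "09:00", end: "14:30", lux: 550, cct: 6500, output_pct: 100}
  - {start: "14:30", end: "15:00", lux: 300, cct: 4200, output_pct: 90}
  - {start: "15:00", end: "16:00", lux: 260, cct: 3400, output_pct: 90}
  - {start: "16:00", end: "18:00", lux: 300, cct: 2700, output_pct: 90}
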