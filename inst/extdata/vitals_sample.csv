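kind,timestamp,value
pulse_bpm,2023-01-02T08:01:55,81
pulse_bpm,2023-01-02T12:01:55,77
pulse_bpm,2023-01-03T07:29:40,79
pulse_bpm,2023-01-04T08:01:21,79
spo2_percent,2023-01-02T08:01:55,92
spo2_percent,2023-01-02T12:01:55,96
spo2_percent,2023-01-03T07:29:40,96
spo2_percent,2023-01-04T08:01:21,95
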