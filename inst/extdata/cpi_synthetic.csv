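year,index
2018,100.0
2019,100.7
2020,100.4
2021,103.5
2022,112.2
2023,116.1
2024,119.4
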