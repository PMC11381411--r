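accession_id,SSR01_102,SSR01_104,SSR01_108,SSR02_151,SSR02_155,SSR02_159,SSR03_200,SSR03_204,SSR03_210,SSR04_090,SSR04_094,SSR04_096
ACC-01,1,0,1,1,0,0,1,1,0,0,1,0
ACC-02,1,0,1,1,0,0,1,1,0,0,1,0
ACC-03,0,1,0,0,1,1,0,0,1,1,0,1
ACC-04,0,1,1,0,1,0,1,0,1,1,0,0
ACC-05,1,1,0,1,1,0,0,1,1,0,0,1
ACC-06,1,1,0,1,?,0,0,1,1,0,1,1
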