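stimulus_auditory,stimulus_visual,response,proportion,count,n_trials
ba,ba,ba,0.97,,
ba,ba,da,,,
ba,ba,ga,,,
ba,da,ba,,,
ba,da,da,,,
ba,da,ga,,,
ba,ga,ba,0.57,,
ba,ga,da,0.40,,
ba,ga,ga,,,
da,ba,ba,,,
da,ba,da,,,
da,ba,ga,,,
da,da,ba,,,
da,da,da,0.97,,
da,da,ga,,,
da,ga,ba,,,
da,ga,da,,,
da,ga,ga,,,
ga,ba,ba,,,
ga,ba,da,0.02,,
ga,ba,ga,0.96,,
ga,da,ba,,,
ga,da,da,,,
ga,da,ga,,,
ga,ga,ba,,,
ga,ga,da,,,
ga,ga,ga,0.97,,
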