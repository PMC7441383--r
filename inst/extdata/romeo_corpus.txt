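Romeo and Juliet
Juliet: Oh happy dagger!
Romeo died by dagger.
“Live free or die”, that’s the New-Hampshire’s motto
Did you know New-Hampshire is in New-England?
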